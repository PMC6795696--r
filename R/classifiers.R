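## Voxel classifiers over the normalized (adc_n, ef_n, ff_n) feature space.
## Gaussian naive Bayes is implemented natively (it is the reference model
## the MRF stage consumes and the target of the brute-force oracle tests);
## the other seven families wrap established implementations behind one
## probability-output contract.

.FAMILIES <- c("LR", "SVM", "NN", "NB", "RF", "kNN", "KDE", "aKDE")

.HP_RANGES <- list(
  LR = c(1e-3, 1e10),   # inverse regularization strength C
  SVM = c(1e-3, 1e5),   # soft-margin penalty C (RBF kernel)
  NN = c(1e-8, 1e5),    # L2 weight-decay alpha
  RF = c(10, 1000),     # number of trees
  kNN = c(10, 1000),    # number of neighbors
  KDE = c(1e-4, 10)     # Gaussian kernel bandwidth (SD)
)

.train_xy <- function(train) {
  df <- if (inherits(train, "training_set")) train$data else train
  x <- as.matrix(df[, c("adc_n", "ef_n", "ff_n")])
  list(x = x, y = as.integer(df$class_id))
}

#' Fit a Gaussian naive-Bayes voxel classifier
#'
#' Per class c and feature d the model stores the sample mean and variance;
#' class priors default to the empirical class frequencies. Variances are
#' floored at `1e-9` times the largest per-feature total variance so that a
#' constant feature cannot produce a degenerate density.
#'
#' @param train a `training_set` or a data.frame with columns `class_id`,
#'   `adc_n`, `ef_n`, `ff_n`.
#' @param priors `"empirical"` (class sample frequencies) or `"uniform"`.
#' @return An object of class `c("gaussian_nb", "habitat_classifier")` with
#'   elements `mu`, `sigma2` (class x feature matrices), `prior`, `classes`,
#'   `var_floor`.
#' @export
fit_gaussian_nb <- function(train, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  xy <- .train_xy(train)
  classes <- sort(unique(xy$y))
  n_c <- vapply(classes, function(k) sum(xy$y == k), integer(1))
  if (any(n_c < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(classes[n_c < 2], collapse = ", "))
  }
  mu <- t(vapply(classes, function(k) colMeans(xy$x[xy$y == k, , drop = FALSE]),
                 numeric(3)))
  sigma2 <- t(vapply(classes, function(k) apply(xy$x[xy$y == k, , drop = FALSE],
                                                2, var), numeric(3)))
  floor_val <- 1e-9 * max(apply(xy$x, 2, var))
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- 1e-18
  sigma2 <- pmax(sigma2, floor_val)
  prior <- if (priors == "empirical") n_c / sum(n_c) else rep(1 / length(classes),
                                                              length(classes))
  dimnames(mu) <- dimnames(sigma2) <- list(classes, c("adc_n", "ef_n", "ff_n"))
  structure(list(family = "NB", hyperparameter = NULL,
                 mu = mu, sigma2 = sigma2, prior = prior,
                 classes = classes, var_floor = floor_val,
                 n_per_class = setNames(n_c, classes)),
            class = c("gaussian_nb", "habitat_classifier"))
}

#' Per-class posterior probabilities
#'
#' Generic probability output shared by all classifier families: one row per
#' query voxel, one column per class the model covers, rows summing to 1.
#' Features outside the unit cube are still scored, but their count is
#' reported in the `n_out_of_domain` attribute.
#'
#' @param model a fitted `habitat_classifier`.
#' @param newdata numeric matrix of feature rows (`adc_n`, `ef_n`, `ff_n`).
#' @return Matrix of class probabilities with `colnames` the class ids.
#' @export
predict_proba <- function(model, newdata) UseMethod("predict_proba")

.finish_proba <- function(p, classes, newdata) {
  p <- p / rowSums(p)
  colnames(p) <- as.character(classes)
  attr(p, "n_out_of_domain") <- sum(apply(newdata < 0 | newdata > 1, 1, any))
  p
}

#' @export
predict_proba.gaussian_nb <- function(model, newdata) {
  newdata <- .as_feature_rows(newdata)
  K <- length(model$classes)
  logp <- matrix(0, nrow(newdata), K)
  for (j in seq_len(K)) {
    lp <- log(model$prior[j])
    for (d in 1:3) {
      lp <- lp + dnorm(newdata[, d], model$mu[j, d], sqrt(model$sigma2[j, d]),
                       log = TRUE)
    }
    logp[, j] <- lp
  }
  m <- apply(logp, 1, max)
  p <- exp(logp - m)
  .finish_proba(p, model$classes, newdata)
}

.as_feature_rows <- function(x) {
  if (inherits(x, "feature_field")) x <- feature_matrix(x)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  x
}

#' Silverman's rule-of-thumb kernel bandwidth
#'
#' h = sigma_hat * (4 / ((d + 2) n))^(1 / (d + 4)) with sigma_hat the mean
#' of the per-dimension sample standard deviations. A zero-spread sample is
#' floored at 1e-4, the lower end of the bandwidth search range.
#'
#' @param samples numeric matrix of feature rows, n >= 2.
#' @param d dimensionality (defaults to `ncol(samples)`).
#' @return Scalar bandwidth (kernel standard deviation).
#' @export
silverman_bandwidth <- function(samples, d = ncol(samples)) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  stopifnot(n >= 2)
  sigma_hat <- mean(apply(samples, 2, sd))
  h <- sigma_hat * (4 / ((d + 2) * n))^(1 / (d + 4))
  max(h, 1e-4)
}

#' Fit a voxel classifier of any supported family
#'
#' One entry point for the eight model families compared in the
#' cross-validation study. Hyperparameters are validated against the search
#' range of each family; `NB` and `aKDE` take none. Stochastic families
#' (`RF`, `NN`) are made reproducible through `seed`.
#'
#' \describe{
#'   \item{LR}{multinomial logistic regression, C = inverse L2 penalty}
#'   \item{SVM}{RBF support vector machine with probability calibration, cost C}
#'   \item{NN}{20-node single-hidden-layer (three-layer) network, weight decay alpha}
#'   \item{NB}{native Gaussian naive Bayes ([fit_gaussian_nb()])}
#'   \item{RF}{random forest, hyperparameter = number of trees}
#'   \item{kNN}{Euclidean k-nearest-neighbor vote fractions, hyperparameter = k}
#'   \item{KDE}{per-class Gaussian kernel density, hyperparameter = bandwidth}
#'   \item{aKDE}{KDE with per-class Silverman bandwidth ([silverman_bandwidth()])}
#' }
#'
#' @param family one of `"LR"`, `"SVM"`, `"NN"`, `"NB"`, `"RF"`, `"kNN"`,
#'   `"KDE"`, `"aKDE"`.
#' @param hyperparameter family hyperparameter, or `NULL` for NB/aKDE.
#' @param train `training_set` or per-voxel data.frame.
#' @param seed integer seed for stochastic fits.
#' @return A fitted `habitat_classifier`.
#' @export
fit_classifier <- function(family, hyperparameter = NULL, train, seed = 1L) {
  family <- match.arg(family, .FAMILIES)
  rng <- .HP_RANGES[[family]]
  if (is.null(rng)) {
    if (!is.null(hyperparameter)) {
      stop(family, " takes no hyperparameter")
    }
  } else {
    if (is.null(hyperparameter)) stop(family, " requires a hyperparameter")
    if (hyperparameter < rng[1] || hyperparameter > rng[2]) {
      stop(sprintf("%s hyperparameter %g outside range [%g, %g]",
                   family, hyperparameter, rng[1], rng[2]))
    }
  }
  xy <- .train_xy(train)
  classes <- sort(unique(xy$y))
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  fit <- switch(family,
    NB = return(fit_gaussian_nb(train)),
    LR = {
      df <- data.frame(y = factor(xy$y, levels = classes), xy$x)
      m <- nnet::multinom(y ~ adc_n + ef_n + ff_n, data = df,
                          decay = 1 / hyperparameter, trace = FALSE,
                          maxit = 300)
      list(model = m)
    },
    SVM = {
      m <- e1071::svm(xy$x, factor(xy$y, levels = classes),
                      cost = hyperparameter, kernel = "radial",
                      probability = TRUE)
      list(model = m)
    },
    NN = {
      y_ind <- nnet::class.ind(factor(xy$y, levels = classes))
      m <- nnet::nnet(xy$x, y_ind, size = 20, decay = hyperparameter,
                      softmax = ncol(y_ind) > 1, entropy = ncol(y_ind) == 1,
                      maxit = 300, trace = FALSE, MaxNWts = 5000)
      list(model = m)
    },
    RF = {
      m <- randomForest::randomForest(xy$x, factor(xy$y, levels = classes),
                                      ntree = as.integer(hyperparameter))
      list(model = m)
    },
    kNN = {
      if (hyperparameter > nrow(xy$x)) {
        stop("kNN neighbors exceed training-set size")
      }
      list(x = xy$x, y = xy$y, k = as.integer(hyperparameter))
    },
    KDE = {
      list(by_class = lapply(classes, function(k) xy$x[xy$y == k, , drop = FALSE]),
           bandwidth = setNames(rep(hyperparameter, length(classes)), classes),
           prior = vapply(classes, function(k) mean(xy$y == k), numeric(1)))
    },
    aKDE = {
      by_class <- lapply(classes, function(k) xy$x[xy$y == k, , drop = FALSE])
      bw <- vapply(by_class, silverman_bandwidth, numeric(1))
      list(by_class = by_class, bandwidth = setNames(bw, classes),
           prior = vapply(classes, function(k) mean(xy$y == k), numeric(1)))
    })
  structure(c(fit, list(family = family, hyperparameter = hyperparameter,
                        classes = classes, seed = seed)),
            class = c(paste0("hm_", tolower(family)), "habitat_classifier"))
}

#' @export
print.habitat_classifier <- function(x, ...) {
  hp <- if (is.null(x$hyperparameter)) "none" else signif(x$hyperparameter, 4)
  cat(sprintf("habitat_classifier [%s], hyperparameter: %s, classes: %s\n",
              x$family, hp, paste(x$classes, collapse = ",")))
  invisible(x)
}

#' @export
predict_proba.hm_lr <- function(model, newdata) {
  newdata <- .as_feature_rows(newdata)
  df <- as.data.frame(newdata)
  names(df) <- c("adc_n", "ef_n", "ff_n")
  p <- predict(model$model, newdata = df, type = "probs")
  if (is.null(dim(p))) {  # two-class multinom returns P(second level)
    p <- cbind(1 - p, p)
  }
  p <- matrix(p, nrow = nrow(newdata))
  .finish_proba(pmax(p, 0), model$classes, newdata)
}

#' @export
predict_proba.hm_svm <- function(model, newdata) {
  newdata <- .as_feature_rows(newdata)
  pr <- predict(model$model, newdata, probability = TRUE)
  p <- attr(pr, "probabilities")
  p <- p[, as.character(model$classes), drop = FALSE]
  .finish_proba(p, model$classes, newdata)
}

#' @export
predict_proba.hm_nn <- function(model, newdata) {
  newdata <- .as_feature_rows(newdata)
  p <- predict(model$model, newdata)
  if (ncol(p) == 1) p <- cbind(1 - p, p)
  .finish_proba(pmax(p, 1e-300), model$classes, newdata)
}

#' @export
predict_proba.hm_rf <- function(model, newdata) {
  newdata <- .as_feature_rows(newdata)
  p <- predict(model$model, newdata, type = "prob")
  p <- p[, as.character(model$classes), drop = FALSE]
  ## an all-zero row cannot occur (votes sum to ntree), no smoothing needed
  .finish_proba(p, model$classes, newdata)
}

#' @export
predict_proba.hm_knn <- function(model, newdata, chunk = 2048L) {
  newdata <- .as_feature_rows(newdata)
  K <- length(model$classes)
  out <- matrix(0, nrow(newdata), K)
  tr <- model$x
  tr_sq <- rowSums(tr^2)
  for (start in seq(1, nrow(newdata), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(newdata))
    q <- newdata[idx, , drop = FALSE]
    ## squared Euclidean distances, queries x training
    d2 <- outer(rowSums(q^2), tr_sq, "+") - 2 * tcrossprod(q, tr)
    for (i in seq_along(idx)) {
      nb <- model$y[order(d2[i, ])[seq_len(model$k)]]
      out[idx[i], ] <- vapply(model$classes, function(k) sum(nb == k),
                              numeric(1)) / model$k
    }
  }
  .finish_proba(pmax(out, 1e-12), model$classes, newdata)
}

.kde_log_density <- function(x_train, query, h, chunk = 2048L) {
  d <- ncol(x_train)
  n <- nrow(x_train)
  const <- -log(n) - d * log(h * sqrt(2 * pi))
  out <- numeric(nrow(query))
  tr_sq <- rowSums(x_train^2)
  for (start in seq(1, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), tr_sq, "+") - 2 * tcrossprod(q, x_train)
    d2[d2 < 0] <- 0
    e <- -d2 / (2 * h^2)
    m <- apply(e, 1, max)
    out[idx] <- m + log(rowSums(exp(e - m))) + const
  }
  out
}

.predict_proba_kde <- function(model, newdata) {
  newdata <- .as_feature_rows(newdata)
  K <- length(model$classes)
  logp <- matrix(0, nrow(newdata), K)
  for (j in seq_len(K)) {
    logp[, j] <- log(model$prior[j]) +
      .kde_log_density(model$by_class[[j]], newdata, model$bandwidth[j])
  }
  m <- apply(logp, 1, max)
  .finish_proba(exp(logp - m), model$classes, newdata)
}

#' @export
predict_proba.hm_kde <- function(model, newdata) .predict_proba_kde(model, newdata)

#' @export
predict_proba.hm_akde <- function(model, newdata) .predict_proba_kde(model, newdata)

#' Classify every voxel of a tumor VOI
#'
#' Scores all VOI voxels valid in the three feature maps and returns both
#' the per-class probability volume (the input to MRF de-noising) and the
#' raw maximum-a-posteriori habitat map. Probability ties are broken toward
#' the lowest class id.
#'
#' @param model fitted `habitat_classifier`.
#' @param features `feature_field` from [normalize_features()].
#' @param voi [mask_volume()] outlining the whole tumor.
#' @return List with `probs` (a `probability_volume`) and `labels`
#'   (a `habitat_map`).
#' @export
classify_volume <- function(model, features, voi) {
  .stop_unless_aligned(features, voi)
  if (!any(voi$membership)) stop("VOI is empty")
  sel <- voi$membership & features$valid
  if (!any(sel)) stop("no VOI voxel is valid in all three feature maps")
  x <- cbind(features$adc_n[sel], features$ef_n[sel], features$ff_n[sel])
  colnames(x) <- c("adc_n", "ef_n", "ff_n")
  p <- predict_proba(model, x)
  probs <- probability_volume(p, sel, model$classes, features$grid)
  labels <- argmax_labels(probs)
  list(probs = probs, labels = labels)
}

#' Per-voxel class probability volume
#'
#' @param p matrix of class probabilities (rows match `which(valid)` in
#'   raster order).
#' @param valid logical 3-D array of scored voxels.
#' @param classes integer class ids (columns of `p`).
#' @param grid shared [voxel_grid()].
#' @return An object of class `probability_volume`: 4-D array
#'   `(nx, ny, nz, K)` plus `valid`, `classes`, `grid`.
#' @export
probability_volume <- function(p, valid, classes, grid) {
  shape <- dim(valid)
  K <- length(classes)
  stopifnot(ncol(p) == K, nrow(p) == sum(valid))
  arr <- array(NA_real_, c(shape, K))
  for (j in seq_len(K)) {
    slab <- array(NA_real_, shape)
    slab[valid] <- p[, j]
    arr[, , , j] <- slab
  }
  structure(list(probs = arr, valid = valid, classes = classes, grid = grid),
            class = "probability_volume")
}

#' @export
print.probability_volume <- function(x, ...) {
  cat(sprintf("probability_volume %s, %d classes, %d scored voxels\n",
              format(x$grid), length(x$classes), sum(x$valid)))
  invisible(x)
}

#' Maximum-probability labels from a probability volume
#'
#' Ties are broken toward the lowest class id.
#'
#' @param probs a `probability_volume`.
#' @return A `habitat_map`: integer label array (NA outside the scored
#'   voxels) plus the grid.
#' @export
argmax_labels <- function(probs) {
  sel <- probs$valid
  p <- .prob_rows(probs)
  lab_idx <- max.col(p, ties.method = "first")
  labels <- array(NA_integer_, dim(sel))
  labels[sel] <- probs$classes[lab_idx]
  habitat_map(labels, probs$grid)
}

.prob_rows <- function(probs) {
  sel <- probs$valid
  p <- vapply(seq_along(probs$classes),
              function(j) probs$probs[, , , j][sel], numeric(sum(sel)))
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)  # single-voxel VOI
  p
}

#' Habitat label map
#'
#' @param labels integer 3-D array of class labels (NA outside the VOI).
#' @param grid a [voxel_grid()].
#' @return An object of class `habitat_map`.
#' @export
habitat_map <- function(labels, grid) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  stopifnot(length(dim(labels)) == 3)
  bad <- labels[!is.na(labels)]
  if (length(bad) && (min(bad) < 1L || max(bad) > 5L)) {
    stop("labels must be in 1..5")
  }
  structure(list(labels = labels, grid = grid), class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  tab <- table(factor(x$labels[!is.na(x$labels)], levels = 1:5))
  cat(sprintf("habitat_map %s\n  voxels per class: %s\n", format(x$grid),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " ")))
  invisible(x)
}

#' Serialize / restore a Gaussian NB model as JSON
#'
#' @param model a `gaussian_nb` model.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `gaussian_nb` (read).
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "gaussian_nb"))
  jsonlite::write_json(list(family = "NB",
                            classes = model$classes,
                            mu = model$mu, sigma2 = model$sigma2,
                            prior = model$prior, var_floor = model$var_floor),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- matrix(unlist(j$mu), ncol = 3)
  sigma2 <- matrix(unlist(j$sigma2), ncol = 3)
  dimnames(mu) <- dimnames(sigma2) <- list(j$classes, c("adc_n", "ef_n", "ff_n"))
  structure(list(family = "NB", hyperparameter = NULL, mu = mu, sigma2 = sigma2,
                 prior = as.numeric(j$prior), classes = as.integer(j$classes),
                 var_floor = j$var_floor),
            class = c("gaussian_nb", "habitat_classifier"))
}
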