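## Markov-random-field de-noising of voxel-wise classifications. The label
## field is modelled with the classifier's per-voxel probabilities as data
## term and a Potts prior penalizing discordant neighbor pairs; the MAP
## labeling is approximated by iterated conditional modes (ICM), a greedy
## sequential update whose energy is non-increasing and which terminates in
## a finite number of sweeps.

#' MRF de-noising configuration
#'
#' @param beta Potts smoothness weight (>= 0); `beta = 0` reduces ICM to the
#'   raw argmax labeling.
#' @param neighborhood `"2d8"` (8-connected within each axial slice, the
#'   default: slices are processed as independent fields) or `"3d6"`
#'   (face-connected 3-D).
#' @param max_iterations maximum ICM sweeps.
#' @param epsilon probability floor keeping the -log data term finite.
#' @return An object of class `mrf_config`.
#' @export
mrf_config <- function(beta = 1.0, neighborhood = c("2d8", "3d6"),
                       max_iterations = 100L, epsilon = 1e-12) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(beta >= 0, max_iterations >= 1, epsilon > 0, epsilon <= 1e-3)
  structure(list(beta = beta, neighborhood = neighborhood,
                 max_iterations = as.integer(max_iterations),
                 epsilon = epsilon),
            class = "mrf_config")
}

.neighbor_shifts <- function(neighborhood) {
  if (neighborhood == "2d8") {
    ## half of the 8-neighborhood: each unordered in-slice pair counted once
    list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  } else {
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  }
}

.shifted_pairs <- function(arr, shift) {
  d <- dim(arr)
  sx <- shift[1]; sy <- shift[2]; sz <- shift[3]
  ix <- seq_len(d[1] - abs(sx)); iy <- seq_len(d[2] - abs(sy))
  iz <- seq_len(d[3] - abs(sz))
  a <- arr[ix + max(sx, 0), iy + max(sy, 0), iz + max(sz, 0), drop = FALSE]
  b <- arr[ix + max(-sx, 0), iy + max(-sy, 0), iz + max(-sz, 0), drop = FALSE]
  list(a = a, b = b)
}

#' Count discordant neighbor pairs of a labeling
#'
#' Each unordered pair of valid neighboring voxels is counted once.
#'
#' @param labels a `habitat_map` (NA voxels are ignored).
#' @param neighborhood `"2d8"` or `"3d6"`.
#' @return Integer pair count.
#' @export
discordant_pairs <- function(labels, neighborhood = "2d8") {
  lab <- labels$labels
  total <- 0L
  for (s in .neighbor_shifts(neighborhood)) {
    p <- .shifted_pairs(lab, s)
    total <- total + sum(p$a != p$b, na.rm = TRUE)
  }
  total
}

#' Energy of a labeling under the MRF model
#'
#' E = sum_v -log(max(p_v(l_v), eps)) + beta * (number of valid neighbor
#' pairs with different labels), each pair counted once. This is the
#' objective ICM descends; it is computed here independently of the ICM
#' sweep code so the two can be cross-checked.
#'
#' @param labels a `habitat_map`.
#' @param probs the `probability_volume` the labels were derived from.
#' @param config an [mrf_config()].
#' @return Scalar energy.
#' @export
labeling_energy <- function(labels, probs, config = mrf_config()) {
  stopifnot(inherits(labels, "habitat_map"), inherits(probs, "probability_volume"))
  .stop_unless_aligned(labels, probs)
  sel <- probs$valid & !is.na(labels$labels)
  lab_sel <- labels$labels[sel]
  if (!all(lab_sel %in% probs$classes)) stop("label outside model classes")
  p <- .prob_rows_at(probs, sel)
  col <- match(lab_sel, probs$classes)
  data_term <- sum(-log(pmax(p[cbind(seq_along(col), col)], config$epsilon)))
  lab <- labels$labels
  lab[!sel] <- NA_integer_
  pair_term <- 0
  for (s in .neighbor_shifts(config$neighborhood)) {
    sp <- .shifted_pairs(lab, s)
    pair_term <- pair_term + sum(sp$a != sp$b, na.rm = TRUE)
  }
  data_term + config$beta * pair_term
}

.prob_rows_at <- function(probs, sel) {
  p <- vapply(seq_along(probs$classes),
              function(j) probs$probs[, , , j][sel], numeric(sum(sel)))
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  p
}

#' De-noise a probability volume by ICM
#'
#' Starts from the argmax labeling and sweeps the voxels in fixed raster
#' order, setting each label to the minimizer of its local energy (ties
#' toward the lowest class id), until a full sweep changes no voxel or the
#' iteration cap is reached. Fully deterministic.
#'
#' @param probs a `probability_volume`.
#' @param config an [mrf_config()].
#' @param voi optional [mask_volume()] restricting the field.
#' @return List with `labels` (a `habitat_map`) and `trace` (a
#'   `convergence_trace`: per-sweep changed-voxel counts, `converged` flag,
#'   `iterations` used).
#' @export
icm_denoise <- function(probs, config = mrf_config(), voi = NULL) {
  sel <- probs$valid
  if (!is.null(voi)) {
    .stop_unless_aligned(probs, voi)
    sel <- sel & voi$membership
  }
  if (!any(sel)) stop("no voxels to de-noise")
  K <- length(probs$classes)
  stopifnot(K <= 64)
  shape <- dim(sel)
  nlp <- -log(pmax(probs$probs, config$epsilon))
  nlp[is.na(nlp)] <- 0
  p <- .prob_rows_at(probs, sel)
  init <- array(0L, shape)
  init[sel] <- max.col(p, ties.method = "first")
  res <- .icm_sweeps(as.numeric(nlp), as.integer(init), as.logical(sel),
                     as.integer(c(shape, K)), config$beta,
                     if (config$neighborhood == "2d8") 0L else 1L,
                     config$max_iterations)
  lab <- array(NA_integer_, shape)
  idx <- array(res$labels, shape)
  lab[sel] <- probs$classes[idx[sel]]
  list(labels = habitat_map(lab, probs$grid),
       trace = convergence_trace(res$trace, res$converged))
}

#' Convergence trace of an ICM run
#'
#' @param changes integer vector: voxels changed at each sweep.
#' @param converged logical; if `TRUE` the trace ends with 0.
#' @return An object of class `convergence_trace`.
#' @export
convergence_trace <- function(changes, converged) {
  changes <- as.integer(changes)
  stopifnot(!converged || changes[length(changes)] == 0L)
  structure(list(changes = changes, converged = converged,
                 iterations = length(changes)),
            class = "convergence_trace")
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("convergence_trace: %d sweep(s), %s\n  changes: %s\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              paste(x$changes, collapse = " ")))
  invisible(x)
}

#' MRF-smooth a whole study
#'
#' With the default 2-D 8-connected neighborhood every axial slice is an
#' independent MRF: each slice intersecting the VOI gets its own ICM run
#' and convergence trace, and the pooled summary reports the median
#' iteration count over slices. With `"3d6"` the study is one 3-D field
#' with a single trace.
#'
#' @param probs a `probability_volume`.
#' @param voi [mask_volume()] outlining the tumor.
#' @param config an [mrf_config()].
#' @return List with `labels` (a `habitat_map`), `traces` (named list, one
#'   `convergence_trace` per slice or one `"volume"` entry),
#'   `median_iterations`, `all_converged` and `empty_slices`.
#' @export
smooth_study <- function(probs, voi, config = mrf_config()) {
  .stop_unless_aligned(probs, voi)
  if (!any(voi$membership)) stop("VOI is empty")
  if (config$neighborhood == "3d6") {
    res <- icm_denoise(probs, config, voi)
    return(list(labels = res$labels, traces = list(volume = res$trace),
                median_iterations = res$trace$iterations,
                all_converged = res$trace$converged,
                empty_slices = integer(0)))
  }
  shape <- probs$grid$shape
  sel <- probs$valid & voi$membership
  lab <- array(NA_integer_, shape)
  traces <- list()
  empty <- integer(0)
  for (z in seq_len(shape[3])) {
    if (!any(sel[, , z])) { empty <- c(empty, z); next }
    slice_probs <- structure(list(
      probs = probs$probs[, , z, , drop = FALSE],
      valid = sel[, , z, drop = FALSE],
      classes = probs$classes,
      grid = voxel_grid(c(shape[1:2], 1L), probs$grid$spacing)),
      class = "probability_volume")
    res <- icm_denoise(slice_probs, config)
    lab[, , z] <- res$labels$labels[, , 1]
    traces[[sprintf("slice_%03d", z)]] <- res$trace
  }
  iters <- vapply(traces, function(t) t$iterations, numeric(1))
  list(labels = habitat_map(lab, probs$grid), traces = traces,
       median_iterations = median(iters),
       all_converged = all(vapply(traces, function(t) t$converged, logical(1))),
       empty_slices = empty)
}

#' Write per-slice convergence traces as CSV
#'
#' @param traces the `traces` element of [smooth_study()].
#' @param path CSV path (columns: slice, iteration, changes).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(names(traces), function(nm) {
    data.frame(slice = nm, iteration = seq_along(traces[[nm]]$changes),
               changes = traces[[nm]]$changes)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
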