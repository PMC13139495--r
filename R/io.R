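#' Save a fitted HMM-GLM (with basis and design statistics) to JSON
#'
#' Full-precision, lossless round trip via [load_model()].
#'
#' @param fit result of [fit_em()] (or a list with at least `params`).
#' @param basis the `rc_basis` used to build designs.
#' @param stats frozen z-score statistics from the training design.
#' @param path output path.
#' @param seed seed recorded for provenance.
#' @export
save_model <- function(fit, basis, stats, path, seed = NA) {
  obj <- list(
    K = fit$params$K, M = fit$params$M, P = fit$params$P,
    modes = fit$params$modes,
    pi = fit$params$pi, alpha = fit$params$alpha,
    W = lapply(fit$params$W, identity),
    basis = list(n_lags = basis$n_lags, n_basis = basis$n_basis,
                 log_offset = basis$log_offset),
    stats = stats, l2 = fit$l2, objective = fit$objective, seed = seed)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path JSON path.
#' @return list with `params` (`hmmglm_params`), `basis`, `stats`, `l2`,
#'   `seed`.
#' @export
load_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(seq_len(o$K), function(k) {
    m <- o$W[[k]]
    matrix(as.numeric(m), nrow = o$M, ncol = o$P, byrow = FALSE)
  })
  # jsonlite returns row-major matrices as R matrices already
  if (is.array(o$W)) W <- lapply(seq_len(dim(o$W)[1]), function(k) o$W[k, , ])
  alpha <- matrix(as.numeric(o$alpha), o$K, o$K, byrow = FALSE)
  if (is.matrix(o$alpha)) alpha <- o$alpha
  params <- hmmglm_params(as.numeric(o$pi), alpha, W, unlist(o$modes))
  basis <- raised_cosine_basis(o$basis$n_lags, o$basis$n_basis,
                               o$basis$log_offset)
  stats <- list(mean = as.numeric(o$stats$mean), sd = as.numeric(o$stats$sd),
                feature_mean = as.numeric(o$stats$feature_mean))
  list(params = params, basis = basis, stats = stats, l2 = o$l2,
       seed = o$seed)
}

SONG_LABEL_CODES <- c(pulse = 1L, sine = 2L, silence = 3L, agonistic = 4L)

#' Read interval song annotations into per-frame labels
#'
#' @param path CSV with columns `onset_s`, `offset_s`, `label` (pulse,
#'   sine, silence, agonistic); uncovered spans are silence.
#' @param frame_rate label rate (default 30).
#' @param duration trial duration in seconds (default: last offset).
#' @return integer label vector (1 pulse, 2 sine, 3 silence, 4 agonistic).
#' @export
read_annotation_csv <- function(path, frame_rate = 30, duration = NULL) {
  iv <- utils::read.csv(path)
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(iv))) stop("annotation CSV must have columns ",
                                      paste(need, collapse = ", "))
  if (is.null(duration)) duration <- max(iv$offset_s)
  n <- ceiling(duration * frame_rate)
  labels <- rep(SONG_LABEL_CODES[["silence"]], n)
  for (i in seq_len(nrow(iv))) {
    code <- SONG_LABEL_CODES[[iv$label[i]]]
    if (is.null(code)) stop("unknown label: ", iv$label[i])
    a <- max(1L, floor(iv$onset_s[i] * frame_rate) + 1L)
    b <- min(n, ceiling(iv$offset_s[i] * frame_rate))
    if (b >= a) labels[a:b] <- code
  }
  labels
}

#' Write per-frame labels as interval annotations
#' @param labels integer label vector.
#' @param path output CSV.
#' @param frame_rate label rate (default 30).
#' @export
write_annotation_csv <- function(labels, path, frame_rate = 30) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  inv <- names(SONG_LABEL_CODES)[r$values]
  utils::write.csv(data.frame(onset_s = (starts - 1) / frame_rate,
                              offset_s = ends / frame_rate,
                              label = inv),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration (YAML)
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
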