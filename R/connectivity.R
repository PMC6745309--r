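#' @title Evoked-response connectivity matrices
#' @description
#' Pairwise Pearson correlation between channel evoked waveforms restricted
#' to the analysis window, aggregation to region-role level, Fisher-z group
#' averaging, and group contrasts with per-entry two-sample tests.
#' @name connectivity
NULL

# internal: constructor + validity checks
connectivity_matrix <- function(values, labels, window_ms, n_subjects = 1L,
                                level = "electrode") {
  stopifnot(nrow(values) == length(labels), ncol(values) == length(labels))
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, window_ms = window_ms,
                 n_subjects = n_subjects, level = level),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d (%s level), n_subjects=%d\n",
              nrow(x$values), ncol(x$values), x$level, x$n_subjects))
  invisible(x)
}

#' Pearson connectivity matrix of an evoked response
#'
#' Pairwise Pearson r between channel waveforms restricted to the analysis
#' window. Channels with zero variance in the window yield missing (`NA`)
#' entries for their pairs, never imputed as 0.
#'
#' @param ev a `tep_evoked` object.
#' @param window_ms analysis window in ms, default `c(15, 300)`.
#' @return a `connectivity_matrix` (symmetric, unit diagonal, entries in
#'   `[-1, 1]` or `NA`).
#' @export
evoked_connectivity <- function(ev, window_ms = c(15, 300)) {
  stopifnot(inherits(ev, "tep_evoked"))
  tt <- ev$times_ms
  idx <- which(tt >= window_ms[1] & tt <= window_ms[2])
  if (length(idx) < 3)
    stop("connectivity window must contain at least 3 samples")
  sub <- t(ev$data[, idx, drop = FALSE])
  sds <- apply(sub, 2, stats::sd)
  r <- suppressWarnings(stats::cor(sub))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r) <- 1
  m <- connectivity_matrix(r, rownames(ev$data), window_ms)
  if (any(sds == 0))
    m$flags <- sprintf("zero-variance channel(s): %s",
                       paste(rownames(ev$data)[sds == 0], collapse = ", "))
  m
}

#' Aggregate an electrode-level connectivity matrix to region-role level
#'
#' Off-diagonal entries are the mean r over all cross pairs between the two
#' groups; diagonal entries are the mean within-group off-diagonal r (a
#' single-electrode group has no within-group pair and is flagged missing).
#'
#' @param m electrode-level `connectivity_matrix`.
#' @param montage `sensor_montage` whose groups cover the matrix labels.
#' @return an 8 x 8 region-role `connectivity_matrix`.
#' @export
region_aggregate <- function(m, montage) {
  stopifnot(inherits(m, "connectivity_matrix"), m$level == "electrode")
  keys <- region_roles(montage)
  n <- length(keys)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gi <- montage$groups[[keys[i]]]
      gj <- montage$groups[[keys[j]]]
      block <- m$values[gi, gj, drop = FALSE]
      if (i == j) {
        if (length(gi) < 2) next  # flagged missing below
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(block)
      }
      out[i, j] <- mean(vals, na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA
  res <- connectivity_matrix(out, keys, m$window_ms, m$n_subjects, "region")
  singles <- keys[vapply(montage$groups, length, 1L) < 2]
  if (length(singles))
    res$flags <- sprintf("single-electrode group(s), diagonal missing: %s",
                         paste(singles, collapse = ", "))
  res
}

#' Fisher-z group average of connectivity matrices
#'
#' Each r is atanh-transformed, averaged across subjects, and
#' back-transformed; entries missing in any input stay missing.
#'
#' @param ms list of `connectivity_matrix` objects with matching labels.
#' @return group-mean `connectivity_matrix` with `n_subjects = length(ms)`.
#' @export
group_mean_matrix <- function(ms) {
  if (!length(ms)) stop("empty list of connectivity matrices")
  labels <- ms[[1]]$labels
  for (m in ms)
    if (!identical(m$labels, labels))
      stop("connectivity matrices have mismatched labels")
  zs <- lapply(ms, function(m) atanh(pmin(pmax(m$values, -1), 1)))
  zbar <- Reduce(`+`, zs) / length(zs)
  r <- tanh(zbar)
  diag(r) <- 1
  connectivity_matrix(r, labels, ms[[1]]$window_ms,
                      n_subjects = length(ms), level = ms[[1]]$level)
}

#' Contrast two groups of connectivity matrices
#'
#' Difference of the Fisher-z group means plus a per-entry unpaired two-
#' sample test on the subjects' Fisher-z values. No multiplicity correction
#' by default; Benjamini-Hochberg optional.
#'
#' @param ms_a,ms_b lists of subject-level `connectivity_matrix` objects.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return list with `difference` (A minus B) and `p_value` matrices,
#'   plus the two group-mean matrices.
#' @export
matrix_contrast <- function(ms_a, ms_b, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  ga <- group_mean_matrix(ms_a)
  gb <- group_mean_matrix(ms_b)
  if (!identical(ga$labels, gb$labels))
    stop("connectivity matrices have mismatched labels")
  labels <- ga$labels
  n <- length(labels)
  diffm <- ga$values - gb$values
  pm <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  can_test <- length(ms_a) >= 2 && length(ms_b) >= 2
  if (can_test) {
    za <- lapply(ms_a, function(m) atanh(pmin(pmax(m$values, -1), 1)))
    zb <- lapply(ms_b, function(m) atanh(pmin(pmax(m$values, -1), 1)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        xa <- vapply(za, function(z) z[i, j], numeric(1))
        xb <- vapply(zb, function(z) z[i, j], numeric(1))
        if (anyNA(xa) || anyNA(xb) || any(!is.finite(c(xa, xb)))) next
        pm[i, j] <- pm[j, i] <- unpaired_t(xa, xb)$p_value
      }
    }
    if (p_adjust == "BH") {
      ut <- upper.tri(pm)
      pm[ut] <- stats::p.adjust(pm[ut], method = "BH")
      pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    }
  }
  list(difference = diffm, p_value = pm, mean_a = ga, mean_b = gb,
       inference = can_test)
}

#' Export a connectivity matrix as labelled CSV
#' @param m a `connectivity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(m, path) {
  df <- as.data.frame(m$values)
  df <- cbind(label = m$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
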