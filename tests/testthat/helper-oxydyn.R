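# Shared fixtures and independent oracles for the test suite.

default_schedule <- function() {
  build_prts_schedule(generate_ternary_msequence(3))
}

noise_free_sd <- c(VO2 = 0, HR = 0, VE = 0, BF = 0, Hacc = 0, CAD = 0)

# Independent brute-force split oracle: enumerate every candidate feature and
# every midpoint between consecutive distinct sorted values, computing SSR by
# direct summation. Ties broken by lowest feature index, then smallest
# threshold (strict improvement required), mirroring the documented contract.
brute_force_split <- function(X, y, candidates = seq_len(ncol(X))) {
  best <- NULL
  for (j in sort(candidates)) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2L) next
    mids <- (v[-length(v)] + v[-1L]) / 2
    for (s in mids) {
      left <- y[X[, j] <= s]
      right <- y[X[, j] > s]
      ssr <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
      if (is.null(best) || ssr < best$ssr) {
        best <- list(feature = j, threshold = s, ssr = ssr)
      }
    }
  }
  best
}

# hand-built leaf-only tree predicting a constant
leaf_tree <- function(value) {
  list(feature = -1L, threshold = 0, left = -1L, right = -1L, value = value)
}

# minimal wide-CSV participant on disk; returns the file paths
write_wide_fixture <- function(dir, n = 120L, drop = NULL) {
  t <- seq(0, n - 1L)
  d <- data.frame(time_s = t, HR = 60 + sin(t / 10), VE = 10 + cos(t / 9),
                  BF = 15 + sin(t / 7), Hacc = 0.5 + 0.1 * sin(t / 5),
                  CAD = 100 + 5 * sin(t / 11), VO2 = 5 + sin(t / 13))
  if (!is.null(drop)) d[[drop]] <- NULL
  path <- file.path(dir, "wide.csv")
  utils::write.csv(d, path, row.names = FALSE)
  seg <- data.frame(label = c("REST", "ADL"), start_s = c(0, 40),
                    end_s = c(40, 100))
  seg_path <- file.path(dir, "segments.csv")
  utils::write.csv(seg, seg_path, row.names = FALSE)
  list(wide = path, segments = seg_path)
}
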