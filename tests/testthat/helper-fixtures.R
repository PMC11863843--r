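# Shared fixtures and independent oracles for the test suite.

# Coarse grids keep network tests fast; the model mechanics are identical
# at any grid resolution.
tiny_grid <- function(step = 100) fg_grid(600, 4000, step)

write_affn_jcamp <- function(path, x, y, yunits = "ABSORBANCE",
                             xunits = "1/CM", extra = character()) {
  n <- length(x)
  lines <- c(
    "##TITLE=test spectrum",
    "##JCAMP-DX=4.24",
    paste0("##XUNITS=", xunits),
    paste0("##YUNITS=", yunits),
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", x[1]),
    paste0("##LASTX=", x[n]),
    paste0("##NPOINTS=", n),
    extra,
    "##XYDATA=(X++(Y..Y))",
    vapply(seq_len(n), function(i)
      paste(format(x[i], digits = 10), format(y[i], digits = 10)),
      character(1)),
    "##END="
  )
  writeLines(lines, path)
  path
}

# Brute-force confusion-matrix oracle: literal per-cell loops, independent
# of the vectorized implementations in R/metrics.R.
brute_confusion <- function(pred, lab) {
  K <- ncol(lab)
  tp <- fp <- fn <- tn <- numeric(K)
  for (j in seq_len(K)) {
    for (i in seq_len(nrow(lab))) {
      if (pred[i, j] == 1 && lab[i, j] == 1) tp[j] <- tp[j] + 1
      if (pred[i, j] == 1 && lab[i, j] == 0) fp[j] <- fp[j] + 1
      if (pred[i, j] == 0 && lab[i, j] == 1) fn[j] <- fn[j] + 1
      if (pred[i, j] == 0 && lab[i, j] == 0) tn[j] <- tn[j] + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

brute_f1 <- function(pred, lab) {
  cm <- brute_confusion(pred, lab)
  ifelse(cm$tp + cm$fp + cm$fn == 0, NA_real_,
         2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
}

brute_fpr_fnr_by_count <- function(pred, lab) {
  n_true <- rowSums(lab == 1)
  out <- list()
  for (k in sort(unique(n_true))) {
    fprs <- fnrs <- numeric(0)
    for (i in which(n_true == k)) {
      fp <- sum(pred[i, ] == 1 & lab[i, ] == 0)
      tn <- sum(pred[i, ] == 0 & lab[i, ] == 0)
      fn <- sum(pred[i, ] == 0 & lab[i, ] == 1)
      tp <- sum(pred[i, ] == 1 & lab[i, ] == 1)
      if (fp + tn > 0) fprs <- c(fprs, fp / (fp + tn))
      if (fn + tp > 0) fnrs <- c(fnrs, fn / (fn + tp))
    }
    out[[as.character(k)]] <- c(fpr = mean(fprs), fnr = mean(fnrs))
  }
  out
}

# Exact Shapley values by subset enumeration (feasible for <= 12 players).
# value_fn(mask) maps a logical inclusion vector to a scalar payoff.
exact_shapley <- function(n_players, value_fn) {
  phi <- numeric(n_players)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n_players))
  vals <- apply(subsets, 1, function(m) value_fn(as.logical(m)))
  sizes <- rowSums(subsets)
  key <- apply(subsets, 1, function(m) paste(as.integer(m), collapse = ""))
  lookup <- stats::setNames(vals, key)
  for (i in seq_len(n_players)) {
    without <- which(!subsets[[i]])
    for (r in without) {
      m <- as.logical(subsets[r, ])
      s <- sizes[r]
      w <- factorial(s) * factorial(n_players - s - 1) /
        factorial(n_players)
      m_with <- m; m_with[i] <- TRUE
      v_with <- lookup[[paste(as.integer(m_with), collapse = "")]]
      phi[i] <- phi[i] + w * (v_with - vals[r])
    }
  }
  phi
}

random_label_matrix <- function(n, K = 17) {
  matrix(rbinom(n * K, 1, 0.3), n, K)
}
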