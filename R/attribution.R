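#' Shapley attribution of a prediction over spectral segments
#'
#' Explains which regions of the spectrum push the model toward predicting
#' the presence (positive values) or absence (negative values) of one
#' functional group. The grid is partitioned into contiguous segments
#' (default 50 1/cm wide — per-point coalitions over thousands of grid
#' points are intractable, and bands are wider than one point anyway), and
#' segment Shapley values are estimated by permutation sampling: for each
#' sampled permutation the segments are revealed one by one, starting from
#' the all-zero spectrum (the post-normalization "no absorbance" state used
#' as masking baseline), and each segment is credited with the change in
#' the class probability it causes. Each segment's value is spread
#' uniformly over its grid points for plotting.
#'
#' Because per-permutation marginal contributions telescope, the segment
#' values sum to f(x) - f(0) up to floating-point error; the residual is
#' recorded on the map.
#'
#' @param params Trained `splitnet_params`.
#' @param spectrum An `ir_spectrum` on the model grid.
#' @param class_index Functional-group index (1-based) or name.
#' @param segment_width Segment width in 1/cm (default 50).
#' @param n_permutations Number of sampled permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return An `attribution_map`: list with `class_index`, `class_name`,
#'   `importance` (per grid point), `segment_values`, `segments`
#'   (data.frame `index`, `wn_lo`, `wn_hi`), `baseline` (model output on
#'   the all-zero spectrum), `fx`, `residual`, `n_permutations`,
#'   `segment_width`, and `degenerate` (TRUE when the model's output does
#'   not react to this spectrum at all, e.g. an untrained model).
#' @export
attribute_spectrum <- function(params, spectrum, class_index,
                               segment_width = 50, n_permutations = 200,
                               seed = 1L) {
  stopifnot(inherits(params, "splitnet_params"),
            inherits(spectrum, "ir_spectrum"))
  if (is.character(class_index)) {
    class_index <- match(class_index, fg_names())
  }
  stopifnot(!is.na(class_index), class_index >= 1,
            class_index <= params$config$n_outputs)
  g <- spectrum$grid
  x <- spectrum$intensities
  n_seg <- max(1L, ceiling((g[length(g)] - g[1]) / segment_width))
  seg_of <- pmin(floor((g - g[1]) / segment_width), n_seg - 1L) + 1L
  # factor levels keep positional indexing valid when a segment holds no
  # grid point (coarse grids); empty segments simply contribute nothing
  seg_pts <- split(seq_along(g), factor(seg_of, levels = seq_len(n_seg)))

  fwd <- function(M) {
    splitnet_forward(params, M, training = FALSE)[, class_index]
  }
  baseline <- unname(fwd(matrix(0, 1, length(g))))
  fx <- unname(fwd(matrix(x, 1)))

  set.seed(seed)
  phi <- numeric(n_seg)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n_seg)
    states <- matrix(0, n_seg, length(g))
    cur <- numeric(length(g))
    for (k in seq_len(n_seg)) {
      pts <- seg_pts[[ord[k]]]
      if (length(pts)) cur[pts] <- x[pts]
      states[k, ] <- cur
    }
    vals <- fwd(states)
    phi[ord] <- phi[ord] + diff(c(baseline, vals))
  }
  phi <- phi / n_permutations

  importance <- numeric(length(g))
  for (s in seq_len(n_seg)) {
    pts <- seg_pts[[s]]
    if (length(pts)) importance[pts] <- phi[s] / length(pts)
  }

  structure(list(
    class_index = class_index,
    class_name = fg_names()[class_index],
    importance = importance,
    segment_values = phi,
    segments = data.frame(
      index = seq_len(n_seg),
      wn_lo = g[1] + (seq_len(n_seg) - 1L) * segment_width,
      wn_hi = pmin(g[1] + seq_len(n_seg) * segment_width, g[length(g)])
    ),
    baseline = baseline,
    fx = fx,
    residual = (fx - baseline) - sum(phi),
    n_permutations = n_permutations,
    segment_width = segment_width,
    degenerate = abs(fx - baseline) < 1e-10
  ), class = "attribution_map")
}

#' Share of positive attribution mass inside a wavenumber window
#'
#' Fraction of the total positive segment Shapley value carried by
#' segments overlapping `[wn_lo, wn_hi]`. Used to check that a model's
#' evidence for a group sits where that group's characteristic bands are.
#'
#' @param map An `attribution_map`.
#' @param wn_lo,wn_hi Window bounds in 1/cm.
#' @return A fraction in `[0, 1]` (NaN when there is no positive mass).
#' @export
positive_attribution_share <- function(map, wn_lo, wn_hi) {
  stopifnot(inherits(map, "attribution_map"))
  pos <- pmax(map$segment_values, 0)
  inside <- map$segments$wn_hi >= wn_lo & map$segments$wn_lo <= wn_hi
  sum(pos[inside]) / sum(pos)
}
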