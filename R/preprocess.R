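#' The fixed analysis wavenumber grid
#'
#' Spectra from different sources cover different wavenumber ranges, so all
#' spectra are standardized onto one fixed grid before modeling. The default
#' runs 600 to 4000 1/cm inclusive at 1 1/cm steps (3401 points): finer than
#' the 8 1/cm resolution of typical reference-library spectra, and coarse
#' enough for a dense network.
#'
#' @param grid_min,grid_max Grid endpoints in 1/cm.
#' @param grid_step Grid spacing in 1/cm.
#' @return Numeric vector of wavenumbers.
#' @export
fg_grid <- function(grid_min = 600, grid_max = 4000, grid_step = 1) {
  stopifnot(grid_min < grid_max, grid_step > 0)
  seq(grid_min, grid_max, by = grid_step)
}

#' Linearly interpolate a raw spectrum onto a grid
#'
#' Piecewise-linear evaluation at each grid point; grid points outside the
#' measured range are filled with 0, the post-normalization neutral value,
#' rather than extrapolated.
#'
#' @param raw A `raw_spectrum`.
#' @param grid Target wavenumber grid (ascending).
#' @return Numeric vector, `length(grid)` intensities.
#' @export
interpolate_to_grid <- function(raw, grid) {
  stopifnot(inherits(raw, "raw_spectrum"))
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  if (length(raw$wavenumbers) < 2L) {
    stop("need at least 2 measured points to interpolate", call. = FALSE)
  }
  out <- stats::approx(raw$wavenumbers, raw$intensities, xout = grid,
                       method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Min-max normalize an intensity vector
#'
#' Rescales to `[0, 1]` as `(v - min) / (max - min)`. A constant vector maps
#' to all zeros (the degenerate case has no spectral contrast to preserve).
#'
#' @param v Finite numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_minmax <- function(v) {
  stopifnot(all(is.finite(v)))
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Construct a preprocessed spectrum object
#'
#' @param grid Wavenumber grid.
#' @param intensities Intensities in `[0, 1]`, same length as `grid`.
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(grid, intensities) {
  stopifnot(length(grid) == length(intensities),
            all(is.finite(intensities)),
            min(intensities) >= 0, max(intensities) <= 1)
  structure(list(grid = grid, intensities = intensities),
            class = "ir_spectrum")
}

#' Preprocess one sample into a dataset record
#'
#' Runs the full per-sample pipeline in fixed order: read the JCAMP-DX
#' file, convert to absorbance, interpolate onto the analysis grid, clip
#' negative absorbances to 0 (baseline artifacts), min-max normalize, and
#' label the functional groups from the SMILES string. Any failure is
#' re-raised with the record id attached.
#'
#' @param jcamp_path Path to the sample's JCAMP-DX file.
#' @param smiles SMILES string of the measured molecule.
#' @param id Record identifier.
#' @param timestamp ISO-8601 timestamp string of the measurement.
#' @param grid Analysis grid (default [fg_grid()]).
#' @return A `dataset_record`: list with `id`, `smiles` (canonical),
#'   `spectrum` (`ir_spectrum`), `labels` (named 0/1 vector of length 17)
#'   and `timestamp`.
#' @export
preprocess_record <- function(jcamp_path, smiles, id,
                              timestamp = NA_character_,
                              grid = fg_grid()) {
  tryCatch({
    raw <- to_absorbance(read_jcampdx(jcamp_path))
    v <- interpolate_to_grid(raw, grid)
    v <- pmax(v, 0)
    v <- normalize_minmax(v)
    structure(
      list(
        id = as.character(id),
        smiles = canonicalize_smiles(smiles),
        spectrum = ir_spectrum(grid, v),
        labels = label_functional_groups(smiles),
        timestamp = timestamp
      ),
      class = "dataset_record"
    )
  }, error = function(e) {
    stop("record '", id, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Keep only the most recent spectrum per molecule
#'
#' Repository data may carry several spectra of the same molecule; later
#' uploads are assumed to supersede earlier ones. Keeps, per canonical
#' SMILES, the record with the latest timestamp; timestamp ties are broken
#' toward the lexicographically larger id so the choice is deterministic.
#'
#' @param records List of `dataset_record`s.
#' @return Filtered list, input order of the kept records preserved.
#' @export
dedup_latest <- function(records) {
  if (length(records) == 0L) return(records)
  smiles <- vapply(records, function(r) r$smiles, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  ts <- vapply(records, function(r) as.character(r$timestamp), character(1))
  tsec <- as.numeric(as.POSIXct(ts, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                               "%Y-%m-%d %H:%M:%S",
                                               "%Y-%m-%d")))
  keep <- logical(length(records))
  for (s in unique(smiles)) {
    i <- which(smiles == s)
    best <- i[order(tsec[i], ids[i], decreasing = TRUE)][1]
    keep[best] <- TRUE
  }
  records[keep]
}

#' Slice a dataset to records containing any of the named groups
#'
#' @param records List of `dataset_record`s.
#' @param groups Character vector of catalog group names.
#' @return Records whose label vector is 1 for at least one named group.
#' @export
slice_subset <- function(records, groups) {
  bad <- setdiff(groups, fg_names())
  if (length(bad) > 0L) {
    stop("unknown functional group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(groups, fg_names())
  records[vapply(records, function(r) any(r$labels[idx] == 1L), logical(1))]
}

#' Automated high-baseline screen
#'
#' Optional replacement for manual visual exclusion of noisy spectra:
#' flags records whose median normalized intensity exceeds a threshold,
#' a crude indicator of a high baseline. Disabled by default in the
#' pipeline; apply explicitly when wanted.
#'
#' @param records List of `dataset_record`s.
#' @param median_max Threshold on the per-spectrum median intensity.
#' @return Records passing the screen.
#' @export
screen_high_baseline <- function(records, median_max = 0.5) {
  records[vapply(records, function(r)
    stats::median(r$spectrum$intensities) <= median_max, logical(1))]
}

#' Stack dataset records into model matrices
#'
#' @param records Non-empty list of `dataset_record`s sharing one grid.
#' @return List with `X` (n x p intensity matrix), `Y` (n x 17 label
#'   matrix), `ids`, and `grid`.
#' @export
records_to_matrices <- function(records) {
  stopifnot(length(records) > 0L)
  grid <- records[[1]]$spectrum$grid
  for (r in records) {
    if (!isTRUE(all.equal(r$spectrum$grid, grid))) {
      stop("records do not share a common grid", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(records, function(r) r$spectrum$intensities))
  Y <- do.call(rbind, lapply(records, function(r) as.numeric(r$labels)))
  colnames(Y) <- fg_names()
  list(X = X, Y = Y,
       ids = vapply(records, function(r) r$id, character(1)),
       grid = grid)
}

#' Preprocess a dataset manifest
#'
#' Reads a tab-separated manifest with columns `id`, `smiles`,
#' `jcamp_path`, `timestamp` and preprocesses every row. Relative JCAMP
#' paths are resolved against the manifest's directory.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param grid Analysis grid.
#' @param dedup Keep only the latest spectrum per molecule (default TRUE).
#' @return List of `dataset_record`s.
#' @export
preprocess_manifest <- function(manifest_path, grid = fg_grid(),
                                dedup = TRUE) {
  m <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "jcamp_path", "timestamp")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$jcamp_path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    preprocess_record(p, m$smiles[i], m$id[i], m$timestamp[i], grid = grid)
  })
  if (dedup) recs <- dedup_latest(recs)
  recs
}

#' Write dataset records as a delimited table
#'
#' One row per record: id, smiles, timestamp, the 17 label columns, then
#' one intensity column per grid point.
#'
#' @param records List of `dataset_record`s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(records, path) {
  mats <- records_to_matrices(records)
  lab <- as.data.frame(mats$Y)
  names(lab) <- paste0("label.", gsub(" ", "_", fg_names()))
  intens <- as.data.frame(mats$X)
  names(intens) <- paste0("wn", mats$grid)
  df <- cbind(
    data.frame(id = mats$ids,
               smiles = vapply(records, function(r) r$smiles, character(1)),
               timestamp = vapply(records, function(r)
                 as.character(r$timestamp), character(1)),
               stringsAsFactors = FALSE),
    lab, intens)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read dataset records from a delimited table written by
#' [write_dataset_tsv()]
#'
#' @param path Input TSV path.
#' @return List of `dataset_record`s.
#' @export
read_dataset_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  lab_cols <- grep("^label\\.", names(df))
  wn_cols <- grep("^wn", names(df))
  grid <- as.numeric(sub("^wn", "", names(df)[wn_cols]))
  lapply(seq_len(nrow(df)), function(i) {
    labels <- as.integer(df[i, lab_cols])
    names(labels) <- fg_names()
    structure(
      list(id = as.character(df$id[i]),
           smiles = df$smiles[i],
           spectrum = ir_spectrum(grid, as.numeric(df[i, wn_cols])),
           labels = labels,
           timestamp = df$timestamp[i]),
      class = "dataset_record")
  })
}
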