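#' Synthetic band catalog
#'
#' Characteristic absorption bands used by the synthetic-spectrum
#' generator: for each functional group, one or more bands given as a
#' center range (the generator draws the actual center uniformly within
#' it), a Gaussian width (sd) and a relative intensity.
#'
#' The bands for the four groups of 4-fluoroanisole follow the worked
#' correlation values for that molecule (methyl C-H stretch 2860-2970,
#' aromatic C-H stretch 3070-3130, C-F stretch 1000-1400, ether C-O
#' stretch 1000-1300). All remaining entries are fixture constants taken
#' from standard IR correlation-table ranges, sometimes narrowed so that
#' each group's band combination stays distinguishable in simulation; they
#' are generator settings, not literature claims.
#'
#' @return data.frame with columns `group`, `center_lo`, `center_hi`,
#'   `width_sd`, `rel_int`.
#' @export
band_catalog <- function() {
  b <- function(group, lo, hi, sd, int)
    data.frame(group = group, center_lo = lo, center_hi = hi,
               width_sd = sd, rel_int = int)
  rbind(
    b("alkane", 2850, 2970, 30, 0.90),
    b("alkane", 1455, 1475, 12, 0.40),
    b("methyl", 2860, 2970, 28, 0.85),
    b("methyl", 1370, 1385, 10, 0.45),
    b("alkene", 3010, 3100, 20, 0.50),
    b("alkene", 1630, 1680, 12, 0.55),
    b("alkyne", 3260, 3320, 15, 0.60),
    b("alkyne", 2100, 2200, 12, 0.50),
    b("alcohols", 3200, 3550, 80, 0.95),
    b("alcohols", 1020, 1150, 25, 0.60),
    b("amines", 3300, 3500, 30, 0.60),
    b("amines", 1590, 1620, 15, 0.55),
    b("nitriles", 2210, 2260, 12, 0.75),
    b("aromatics", 3070, 3130, 18, 0.45),
    b("aromatics", 1580, 1615, 10, 0.50),
    b("aromatics", 1450, 1510, 10, 0.50),
    b("aromatics", 670, 900, 20, 0.80),
    b("alkyl halides", 1000, 1400, 18, 0.85),
    b("alkyl halides", 620, 800, 15, 0.70),
    b("esters", 1735, 1750, 10, 0.95),
    b("esters", 1160, 1290, 20, 0.80),
    b("ketones", 1705, 1725, 10, 0.90),
    b("aldehydes", 1720, 1740, 10, 0.90),
    b("aldehydes", 2695, 2830, 18, 0.45),
    b("carboxylic acids", 1700, 1725, 12, 0.90),
    b("carboxylic acids", 2500, 3300, 150, 0.70),
    b("ether", 1000, 1300, 22, 0.85),
    b("acyl halides", 1785, 1815, 10, 0.95),
    b("amides", 1640, 1690, 12, 0.90),
    b("amides", 3150, 3350, 35, 0.55),
    b("nitro", 1500, 1560, 12, 0.85),
    b("nitro", 1300, 1360, 12, 0.70)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the gross features of real IR compilations: one to
#' five functional groups per molecule drawn uniformly (real libraries
#' peak at three to four groups per sample, ranging from zero up to about
#' nine), modest white noise, and slow baseline drift.
#'
#' @param n Number of samples.
#' @param count_min,count_max Range of the per-sample group count
#'   (uniform; default 1 to 5).
#' @param noise_sd Standard deviation of additive white noise
#'   (default 0.02, pre-normalization intensity units).
#' @param drift_amp Amplitude of the smooth sinusoidal baseline drift
#'   (default 0.05).
#' @param grid Analysis grid (default [fg_grid()]).
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 100, count_min = 1, count_max = 5,
                       noise_sd = 0.02, drift_amp = 0.05,
                       grid = fg_grid(), seed = 7L) {
  stopifnot(n >= 1, count_min >= 0, count_max >= count_min,
            count_max <= fg_count(), noise_sd >= 0, drift_amp >= 0)
  structure(list(n = as.integer(n), count_min = as.integer(count_min),
                 count_max = as.integer(count_max), noise_sd = noise_sd,
                 drift_amp = drift_amp, grid = grid,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate one synthetic IR spectrum for a label vector
#'
#' Sums one Gaussian peak per band of every present group (center drawn
#' uniformly within the band's range, amplitude jittered by +-20%), adds a
#' slow sinusoidal baseline drift and white noise, then min-max
#' normalizes, yielding intensities in `[0, 1]`. Deterministic given
#' `seed`. All-zero labels with zero noise and drift yield the flat zero
#' spectrum.
#'
#' @param labels 0/1 vector of length 17 in catalog order.
#' @param config A [sim_config()].
#' @param seed Per-spectrum seed.
#' @return An `ir_spectrum`.
#' @export
generate_spectrum <- function(labels, config = sim_config(), seed = 1L) {
  stopifnot(length(labels) == fg_count(), all(labels %in% c(0, 1)))
  set.seed(seed)
  g <- config$grid
  y <- numeric(length(g))
  bands <- band_catalog()
  present <- fg_names()[labels == 1]
  for (i in seq_len(nrow(bands))) {
    if (!(bands$group[i] %in% present)) next
    center <- stats::runif(1, bands$center_lo[i], bands$center_hi[i])
    amp <- bands$rel_int[i] * stats::runif(1, 0.8, 1.2)
    y <- y + amp * exp(-0.5 * ((g - center) / bands$width_sd[i])^2)
  }
  if (config$drift_amp > 0) {
    period <- stats::runif(1, 2000, 6000)
    phase <- stats::runif(1, 0, 2 * pi)
    y <- y + config$drift_amp *
      (1 + sin(2 * pi * (g - g[1]) / period + phase)) / 2
  }
  if (config$noise_sd > 0) {
    y <- y + stats::rnorm(length(g), 0, config$noise_sd)
  }
  ir_spectrum(g, normalize_minmax(y))
}

#' Generate a labeled synthetic dataset
#'
#' Draws, per sample, a group count uniform on
#' `[count_min, count_max]`, then that many distinct groups uniformly from
#' the catalog, and synthesizes the spectrum with [generate_spectrum()].
#' Records carry synthetic ids and an `NA` SMILES marker.
#'
#' @param config A [sim_config()].
#' @return List of `config$n` `dataset_record`s.
#' @export
generate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  counts <- sample(seq(config$count_min, config$count_max),
                   config$n, replace = TRUE)
  group_draws <- lapply(counts, function(k) sample.int(fg_count(), k))
  lapply(seq_len(config$n), function(i) {
    labels <- integer(fg_count())
    labels[group_draws[[i]]] <- 1L
    names(labels) <- fg_names()
    structure(
      list(id = sprintf("syn%06d", i),
           smiles = NA_character_,
           spectrum = generate_spectrum(labels, config,
                                        seed = config$seed + 7919L * i),
           labels = labels,
           timestamp = "2026-01-01T00:00:00"),
      class = "dataset_record")
  })
}

#' Fixture molecules with hand-audited labels
#'
#' A panel of small molecules covering every catalog group at least
#' twice, each with its expected 17-bit label vector. The expected labels
#' were pre-computed with an independent substructure-matching toolkit and
#' hand-audited; they serve as an oracle for [label_functional_groups()].
#' Includes 4-fluoroanisole (methyl, aromatics, alkyl halides, ether),
#' methyl acetate (ester but not ether under the corrected pattern),
#' acetonitrile, acetyl chloride, benzamide and nitromethane.
#'
#' Notes on the pinned catalog semantics visible in this panel: a methyl
#' carbon attached to carbon also counts as alkane; halogen on an aromatic
#' or carbonyl carbon counts as alkyl halide.
#'
#' @return data.frame with columns `name`, `smiles`, and one 0/1 column
#'   per functional group (catalog order, spaces replaced by `_`).
#' @export
fixture_molecules <- function() {
  # columns: alkane methyl alkene alkyne alcohols amines nitriles aromatics
  #          alkyl_halides esters ketones aldehydes carboxylic_acids ether
  #          acyl_halides amides nitro
  rows <- list(
    list("hexane", "CCCCCC",                 c(1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("cyclohexane", "C1CCCCC1",          c(1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("isobutylene", "CC(C)=C",           c(1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("1-hexene", "C=CCCCC",              c(1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("propyne", "CC#C",                  c(1,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("1-butyne", "C#CCC",                c(1,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("ethanol", "CCO",                   c(1,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("2-propanol", "CC(C)O",             c(1,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0)),
    list("phenol", "Oc1ccccc1",              c(0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0)),
    list("ethylamine", "CCN",                c(1,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0)),
    list("aniline", "Nc1ccccc1",             c(0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0)),
    list("acetonitrile", "CC#N",             c(1,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0)),
    list("benzonitrile", "N#Cc1ccccc1",      c(0,0,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0)),
    list("benzene", "c1ccccc1",              c(0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0)),
    list("toluene", "Cc1ccccc1",             c(1,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0)),
    list("chloroethane", "CCCl",             c(1,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0)),
    list("bromobenzene", "Brc1ccccc1",       c(0,0,0,0,0,0,0,1,1,0,0,0,0,0,0,0,0)),
    list("4-fluoroanisole", "COc1ccc(F)cc1", c(0,1,0,0,0,0,0,1,1,0,0,0,0,1,0,0,0)),
    list("methyl acetate", "CC(=O)OC",       c(1,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0)),
    list("ethyl benzoate", "CCOC(=O)c1ccccc1",
                                             c(1,1,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0)),
    list("methyl methoxyacetate", "COCC(=O)OC",
                                             c(0,1,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0)),
    list("acetone", "CC(C)=O",               c(1,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0)),
    list("acetophenone", "CC(=O)c1ccccc1",   c(1,1,0,0,0,0,0,1,0,0,1,0,0,0,0,0,0)),
    list("acetaldehyde", "CC=O",             c(1,1,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0)),
    list("benzaldehyde", "O=Cc1ccccc1",      c(0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0)),
    list("acetic acid", "CC(=O)O",           c(1,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0)),
    list("benzoic acid", "OC(=O)c1ccccc1",   c(0,0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0)),
    list("diethyl ether", "CCOCC",           c(1,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0)),
    list("anisole", "COc1ccccc1",            c(0,1,0,0,0,0,0,1,0,0,0,0,0,1,0,0,0)),
    list("acetyl chloride", "CC(=O)Cl",      c(1,1,0,0,0,0,0,0,1,0,0,0,0,0,1,0,0)),
    list("benzoyl chloride", "O=C(Cl)c1ccccc1",
                                             c(0,0,0,0,0,0,0,1,1,0,0,0,0,0,1,0,0)),
    list("acetamide", "CC(N)=O",             c(1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0)),
    list("benzamide", "NC(=O)c1ccccc1",      c(0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0)),
    list("nitromethane", "C[N+](=O)[O-]",    c(0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1)),
    list("nitrobenzene", "O=[N+]([O-])c1ccccc1",
                                             c(0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1)),
    list("4-chlorobenzonitrile", "Clc1ccc(C#N)cc1",
                                             c(0,0,0,0,0,0,1,1,1,0,0,0,0,0,0,0,0)),
    list("allyl bromide", "C=CCBr",          c(0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0))
  )
  lab <- do.call(rbind, lapply(rows, function(r) r[[3]]))
  colnames(lab) <- gsub(" ", "_", fg_names())
  cbind(data.frame(name = vapply(rows, `[[`, character(1), 1),
                   smiles = vapply(rows, `[[`, character(1), 2),
                   stringsAsFactors = FALSE),
        as.data.frame(lab))
}

#' Write a synthetic dataset as JCAMP-DX files plus manifest
#'
#' @param records List of `dataset_record`s (e.g. from
#'   [generate_dataset()]).
#' @param out_dir Output directory (created if missing).
#' @return Path of the written manifest, invisibly.
#' @export
write_synthetic_jcamp <- function(records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(records, function(r) {
    p <- file.path(out_dir, paste0(r$id, ".jdx"))
    write_jcampdx(r$spectrum$grid, r$spectrum$intensities, p,
                  title = r$id, y_units = "absorbance")
    p
  }, character(1))
  lab <- do.call(rbind, lapply(records, function(r) as.integer(r$labels)))
  colnames(lab) <- paste0("label.", gsub(" ", "_", fg_names()))
  manifest <- cbind(
    data.frame(id = vapply(records, function(r) r$id, character(1)),
               jcamp_path = basename(paths),
               timestamp = vapply(records, function(r)
                 as.character(r$timestamp), character(1)),
               stringsAsFactors = FALSE),
    as.data.frame(lab))
  mpath <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}
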