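#' Configuration for the synthetic fixture generators
#'
#' Every generator is a pure function of this config: the seed fully
#' determines the output bytes. Defaults describe a small desk-scale world
#' — a 3-chromosome 1 Mb genome with 50 genes per chromosome, a 1 kb-step
#' signal track, 100 peaks, and a 100-feature x 20-sample expression
#' matrix with a 2-unit group shift (a tumor-vs-normal style effect on a
#' log-expression-like scale).
#'
#' @param seed Integer RNG seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bases.
#' @param n_genes Genes per chromosome.
#' @param signal_step Signal tile width in bases.
#' @param n_peaks Peaks per chromosome.
#' @param n_features Expression features (rows).
#' @param n_samples Expression samples (columns); half are "case".
#' @param group_effect Mean shift added to case samples.
#' @param signal_sd Random-walk innovation standard deviation.
#' @param noise_sd Expression residual standard deviation.
#' @return An object of class `FixtureConfig`.
#' @export
fixture_config <- function(seed = 42L, n_chroms = 3L, chrom_length = 1e6,
                           n_genes = 50L, signal_step = 1000L,
                           n_peaks = 100L, n_features = 100L,
                           n_samples = 20L, group_effect = 2,
                           signal_sd = 0.5, noise_sd = 1) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.double(chrom_length),
              n_genes = as.integer(n_genes),
              signal_step = as.double(signal_step),
              n_peaks = as.integer(n_peaks),
              n_features = as.integer(n_features),
              n_samples = as.integer(n_samples),
              group_effect = as.double(group_effect),
              signal_sd = as.double(signal_sd),
              noise_sd = as.double(noise_sd))
  if (any(vapply(cfg[c("n_chroms", "n_genes", "n_peaks", "n_features",
                       "n_samples")], `<`, TRUE, 0))) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "FixtureConfig")
}

# run fn with a derived deterministic seed, restoring the caller's RNG state
with_fixture_seed <- function(config, offset, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed((config$seed * 1009L + offset) %% .Machine$integer.max)
  fn()
}

chrom_names <- function(n) {
  base <- c(as.character(1:22), "X", "Y")
  nm <- if (n <= length(base)) base[seq_len(n)] else
    c(base, as.character(seq(25L, length.out = n - length(base))))
  paste0("chr", nm)
}

chrom_offset <- function(config, chrom) {
  match(chrom, chrom_names(config$n_chroms))
}

#' Generate the fixture genome
#'
#' `n_chroms` chromosomes of equal length named `chr1..chr22, chrX, chrY`
#' in order.
#'
#' @param config A [fixture_config()].
#' @return A [seq_info()] table.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  if (config$n_chroms == 0L) return(seq_info())
  seq_info(chrom_names(config$n_chroms),
           rep(config$chrom_length, config$n_chroms))
}

#' Generate a continuous signal track
#'
#' Fixed-step tiles covering the chromosome, with values from a seeded
#' bounded random walk (reflected into [-3, 3]) — smooth structure that
#' emulates methylation or ChIP fold-change signal rather than white
#' noise, so line tracks and summarization show visible features.
#'
#' @param config A [fixture_config()].
#' @param chrom Chromosome name from [make_genome()].
#' @return A list with `text` (bedGraph lines) and `table` (the ground
#'   truth `ColumnTable`, value column `"signal"`); both agree exactly.
#' @export
make_signal_track <- function(config, chrom) {
  stopifnot(inherits(config, "FixtureConfig"))
  off <- chrom_offset(config, chrom)
  if (is.na(off)) stop("unknown fixture chromosome: ", chrom, call. = FALSE)
  starts <- seq(0, config$chrom_length - 1, by = config$signal_step)
  ends <- pmin(starts + config$signal_step, config$chrom_length)
  n <- length(starts)
  vals <- with_fixture_seed(config, 100L + off, function() {
    steps <- stats::rnorm(n, sd = config$signal_sd)
    v <- cumsum(steps)
    # reflect into [-3, 3] to keep the walk bounded
    period <- 12
    w <- (v + 3) %% (2 * period / 2)
    ifelse(w > 6, 12 - w, w) - 3
  })
  vals <- round(vals, 4)
  tab <- make_column_table(rep(chrom, n), starts, ends,
                           values = list(signal = vals))
  list(text = write_bedgraph(tab), table = tab)
}

#' Generate non-overlapping scored peaks
#'
#' `n_peaks` sorted, pairwise non-overlapping intervals with integer
#' scores in [1, 1000], emulating ChIP-seq peak calls for a stacked-blocks
#' track.
#'
#' @param config A [fixture_config()].
#' @param chrom Chromosome name.
#' @return A list with `text` (BED5 lines) and `table` (ground truth).
#' @export
make_peaks <- function(config, chrom) {
  stopifnot(inherits(config, "FixtureConfig"))
  off <- chrom_offset(config, chrom)
  if (is.na(off)) stop("unknown fixture chromosome: ", chrom, call. = FALSE)
  n <- config$n_peaks
  if (n == 0L) {
    tab <- make_column_table(values = list(score = double()),
                             strings = list(name = character()))
    return(list(text = character(), table = tab))
  }
  gen <- with_fixture_seed(config, 200L + off, function() {
    width <- pmax(50, round(stats::rexp(n, rate = 1 / 400)))
    gap <- pmax(1, round(stats::rexp(n, rate = n / config$chrom_length)))
    starts <- cumsum(gap) + cumsum(c(0, width[-n]))
    # rescale into the chromosome if the draw overshoots
    max_end <- starts[n] + width[n]
    if (max_end > config$chrom_length) {
      scale <- config$chrom_length / (max_end + 1)
      starts <- floor(starts * scale)
      width <- pmax(1, floor(width * scale))
      # scaling can break the non-overlap guarantee; sweep and keep
      keep <- logical(length(starts))
      last_end <- -1
      for (i in seq_along(starts)) {
        if (starts[i] >= last_end) {
          keep[i] <- TRUE
          last_end <- starts[i] + width[i]
        }
      }
      starts <- starts[keep]; width <- width[keep]
    }
    list(starts = starts, width = width,
         score = sample(1:1000, length(starts), replace = TRUE))
  })
  starts <- gen$starts
  ends <- starts + gen$width
  tab <- make_column_table(rep(chrom, length(starts)), starts, ends,
                           values = list(score = as.double(gen$score)),
                           strings = list(name = paste0(chrom, "_peak",
                                                        seq_along(starts))))
  list(text = write_bed(tab), table = tab)
}

#' Generate gene models and their GFF3
#'
#' `n_genes` non-overlapping genes tiled across the chromosome, each with
#' 1-5 exons and a random strand.
#'
#' @param config A [fixture_config()].
#' @param chrom Chromosome name.
#' @return A list with `text` (GFF3 lines) and `genes` (list of
#'   [gene_model()]).
#' @export
make_gene_models <- function(config, chrom) {
  stopifnot(inherits(config, "FixtureConfig"))
  off <- chrom_offset(config, chrom)
  if (is.na(off)) stop("unknown fixture chromosome: ", chrom, call. = FALSE)
  n <- config$n_genes
  if (n == 0L) return(list(text = write_gff3(list()), genes = list()))
  slot <- floor(config$chrom_length / n)
  genes <- with_fixture_seed(config, 300L + off, function() {
    lapply(seq_len(n), function(i) {
      lo <- (i - 1) * slot
      g_start <- lo + sample.int(max(slot %/% 4, 1), 1) - 1
      g_len <- max(200, sample.int(max(slot %/% 2, 200), 1))
      g_end <- min(g_start + g_len, lo + slot - 1)
      n_ex <- sample.int(5, 1)
      n_bounds <- min(2 * n_ex, g_end - g_start)
      n_bounds <- n_bounds - n_bounds %% 2   # even count: start/end pairs
      bounds <- sort(sample(seq(g_start, g_end), n_bounds))
      if (n_bounds >= 2L) {
        ex_s <- bounds[seq(1, n_bounds - 1, by = 2)]
        ex_e <- bounds[seq(2, n_bounds, by = 2)]
      } else {
        ex_s <- ex_e <- double()
      }
      keep <- ex_e > ex_s
      gene_model(sprintf("GENE%s_%03d", sub("^chr", "", chrom), i),
                 genomic_range(chrom, g_start, g_end),
                 strand = sample(c("+", "-"), 1),
                 exon_starts = ex_s[keep], exon_ends = ex_e[keep])
    })
  })
  list(text = write_gff3(genes), genes = genes)
}

#' Generate an expression matrix with a known group effect
#'
#' `n_features` features placed at the fixture gene locations (cycling
#' through chromosomes) by `n_samples` samples; the second half of the
#' samples ("case") get `group_effect` added to every feature. Residuals
#' are i.i.d. normal with `noise_sd`. The returned ground truth carries
#' the group labels and the true effect so parameter-recovery tests can
#' compare estimates against it.
#'
#' @param config A [fixture_config()].
#' @return A list with `text` (feature-matrix lines), `table` (ground
#'   truth `ColumnTable`), `group` (character vector `"control"`/`"case"`
#'   per sample) and `effect` (the true shift).
#' @export
make_expression <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  n_feat <- config$n_features
  n_samp <- config$n_samples
  chroms <- chrom_names(config$n_chroms)
  samples <- sprintf("sample%02d", seq_len(n_samp))
  group <- rep(c("control", "case"), c(ceiling(n_samp / 2), floor(n_samp / 2)))
  if (n_feat == 0L || n_samp == 0L) {
    tab <- make_column_table(
      values = stats::setNames(rep(list(double()), n_samp), samples),
      strings = list(feature_name = character()))
    return(list(text = write_feature_matrix(tab), table = tab,
                group = group, effect = config$group_effect))
  }
  # feature coordinates: gene slots cycled across chromosomes
  slot <- floor(config$chrom_length / max(config$n_genes, 1L))
  idx <- seq_len(n_feat) - 1L
  chrom <- chroms[(idx %% config$n_chroms) + 1L]
  gi <- (idx %/% config$n_chroms) %% max(config$n_genes, 1L)
  starts <- gi * slot
  ends <- starts + max(slot %/% 2, 1)
  vals <- with_fixture_seed(config, 400L, function() {
    base <- stats::rnorm(n_feat, mean = 8, sd = 2)
    m <- matrix(stats::rnorm(n_feat * n_samp, sd = config$noise_sd),
                n_feat, n_samp) + base
    m[, group == "case"] <- m[, group == "case"] + config$group_effect
    round(m, 4)
  })
  tab <- make_column_table(chrom, starts, ends,
                           values = stats::setNames(
                             lapply(seq_len(n_samp), function(j) vals[, j]),
                             samples),
                           strings = list(feature_name = sprintf("feat%04d",
                                                                 seq_len(n_feat))))
  list(text = write_feature_matrix(tab), table = tab, group = group,
       effect = config$group_effect)
}

#' Write a full fixture set to disk
#'
#' One bedGraph, BED and GFF3 per chromosome, one expression matrix, and a
#' ready `sources.json` config consumable by [load_sources_config()].
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path to the written `sources.json`, invisibly.
#' @export
write_fixtures <- function(config, out_dir) {
  stopifnot(inherits(config, "FixtureConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(config)
  entries <- list()
  for (chrom in genome$chrom) {
    sig <- make_signal_track(config, chrom)
    writeLines(sig$text, file.path(out_dir, paste0(chrom, "_signal.bedgraph")))
    entries <- c(entries, list(list(
      id = paste0("signal_", chrom), format = "bedgraph",
      path = paste0(chrom, "_signal.bedgraph"), column_name = "signal")))
    pk <- make_peaks(config, chrom)
    writeLines(pk$text, file.path(out_dir, paste0(chrom, "_peaks.bed")))
    entries <- c(entries, list(list(
      id = paste0("peaks_", chrom), format = "bed",
      path = paste0(chrom, "_peaks.bed"))))
    gm <- make_gene_models(config, chrom)
    writeLines(gm$text, file.path(out_dir, paste0(chrom, "_genes.gff3")))
    entries <- c(entries, list(list(
      id = paste0("genes_", chrom), format = "gff3",
      path = paste0(chrom, "_genes.gff3"))))
  }
  expr <- make_expression(config)
  writeLines(expr$text, file.path(out_dir, "expression.tsv"))
  entries <- c(entries, list(list(
    id = "expression", format = "feature_matrix", path = "expression.tsv")))
  cfg <- list(seqinfo = stats::setNames(as.list(genome$length), genome$chrom),
              datasources = entries)
  cfg_path <- file.path(out_dir, "sources.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}
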