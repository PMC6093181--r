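#' Configuration for a synthetic parallel-factor / spike-in experiment
#'
#' Describes a two-condition ChIP-seq experiment with the statistical
#' structure the reference-peak method assumes: control and spike-in peaks
#' are biologically unchanged between conditions (their treated counts carry
#' only the global efficiency bias `true_treated_scaling` plus NB noise),
#' while a fraction of target peaks receive true effects drawn from a
#' unidirectional-loss distribution (`log2FC = -|Normal(effect_mean,
#' effect_sd)|`), mirroring the near-global loss of a degraded transcription
#' factor. Per-peak expected counts are lognormal; counts are negative
#' binomial with `variance = mu + dispersion * mu^2`.
#'
#' `competition_mode` reproduces the spike-in failure mode of a
#' cross-reacting antibody: when the target signal collapses, the spike-in
#' chromatin competes less for antibody, so spike-in treated means are
#' multiplied by `1 + kappa * (1 - relative_target_signal)` — the spike-in
#' channel then reports a biased coefficient while an internal control does
#' not.
#'
#' @param n_target_peaks,n_control_peaks,n_spikein_peaks peak counts per
#'   channel (>= 0; target + control must be >= 1).
#' @param replicates replicates per condition (>= 1).
#' @param true_treated_scaling global efficiency multiplier `s*` applied to
#'   every treated library (> 0). Values < 1 emulate reduced recovery, as
#'   seen as a through-origin gradient < 1 over control peaks; values > 1
#'   emulate read redistribution inflating treated counts.
#' @param fraction_changed fraction of target peaks with a true effect, in
#'   `[0, 1]`.
#' @param effect_mean,effect_sd parameters of the loss-effect magnitude
#'   distribution `|Normal(effect_mean, effect_sd)|` (log2 units).
#' @param mean_log,mean_sdlog lognormal parameters of the per-peak expected
#'   counts; defaults `log(100)` and `0.5` give a median of about 100 with a
#'   modest spread typical of a filtered high-confidence reference set.
#' @param dispersion NB dispersion `alpha` (default 0.05).
#' @param competition_mode logical; see above.
#' @param kappa competition strength (default 1).
#' @param background_depth constant per-library background read count added
#'   to the in-peak sum to form `library_totals` (ChIP libraries are
#'   background-dominated, so totals barely reflect in-peak signal).
#' @param spikein_prefix chromosome-name prefix of the spike-in species.
#' @param seed RNG seed (mandatory).
#' @return A validated `refchip_sim_config` list.
#' @export
simulation_config <- function(n_target_peaks = 10000L,
                              n_control_peaks = 50000L,
                              n_spikein_peaks = 2000L,
                              replicates = 3L,
                              true_treated_scaling = 0.8,
                              fraction_changed = 0.8,
                              effect_mean = 2, effect_sd = 0.5,
                              mean_log = log(100), mean_sdlog = 0.5,
                              dispersion = 0.05,
                              competition_mode = FALSE, kappa = 1,
                              background_depth = 2e6,
                              spikein_prefix = "dm3_",
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  cfg <- list(n_target_peaks = as.integer(n_target_peaks),
              n_control_peaks = as.integer(n_control_peaks),
              n_spikein_peaks = as.integer(n_spikein_peaks),
              replicates = as.integer(replicates),
              true_treated_scaling = true_treated_scaling,
              fraction_changed = fraction_changed,
              effect_mean = effect_mean, effect_sd = effect_sd,
              mean_log = mean_log, mean_sdlog = mean_sdlog,
              dispersion = dispersion,
              competition_mode = isTRUE(competition_mode), kappa = kappa,
              background_depth = background_depth,
              spikein_prefix = spikein_prefix,
              seed = as.integer(seed))
  with(cfg, {
    if (n_target_peaks < 0 || n_control_peaks < 0 || n_spikein_peaks < 0 ||
        n_target_peaks + n_control_peaks < 1) {
      stop("need non-negative peak counts and >= 1 target or control peak",
           call. = FALSE)
    }
    if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
    if (true_treated_scaling <= 0) {
      stop("true_treated_scaling must be > 0", call. = FALSE)
    }
    if (fraction_changed < 0 || fraction_changed > 1) {
      stop("fraction_changed must lie in [0, 1]", call. = FALSE)
    }
    if (dispersion <= 0 || mean_sdlog < 0 || effect_sd < 0 || kappa < 0) {
      stop("dispersion/effect_sd/mean_sdlog/kappa out of range", call. = FALSE)
    }
  })
  structure(cfg, class = "refchip_sim_config")
}

#' Generate a synthetic experiment
#'
#' Draws peak coordinates, a counts matrix, a sample sheet and a truth table
#' from a [simulation_config()]. Target and control peaks are laid out
#' alternately along synthetic main-species chromosomes with 1600 bp gaps
#' (well beyond the 500 bp exclusion radius); spike-in peaks live on
#' prefixed chromosomes. The truth table records every peak's true
#' biological log2 fold-change (the efficiency bias `s*` is technical and
#' excluded). Fully reproducible: the same config yields bit-identical
#' output.
#'
#' @param config a `refchip_sim_config`.
#' @return A list: `counts` (`refchip_counts` with library totals), `peaks`
#'   (named list of `refchip_peaks` per channel), `samples`
#'   (`refchip_samples`: conditions `control`/`treated`), `truth`
#'   (data frame `name`, `channel`, `true_log2fc`, `mean`), and `channels`
#'   (named channel vector for [ma_transform()]).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "refchip_sim_config"))
  cf <- config
  set.seed(cf$seed)
  n_t <- cf$n_target_peaks; n_c <- cf$n_control_peaks; n_s <- cf$n_spikein_peaks
  reps <- cf$replicates

  nm_t <- if (n_t) sprintf("target_%05d", seq_len(n_t)) else character(0)
  nm_c <- if (n_c) sprintf("ctrl_%05d", seq_len(n_c)) else character(0)
  nm_s <- if (n_s) sprintf("spike_%05d", seq_len(n_s)) else character(0)

  mu_t <- stats::rlnorm(n_t, cf$mean_log, cf$mean_sdlog)
  mu_c <- stats::rlnorm(n_c, cf$mean_log, cf$mean_sdlog)
  mu_s <- stats::rlnorm(n_s, cf$mean_log, cf$mean_sdlog)

  lfc_t <- numeric(n_t)
  n_changed <- round(cf$fraction_changed * n_t)
  if (n_changed > 0) {
    changed <- sample.int(n_t, n_changed)
    lfc_t[changed] <- -abs(stats::rnorm(n_changed, cf$effect_mean, cf$effect_sd))
  }

  sstar <- cf$true_treated_scaling
  mu_t_treated <- mu_t * 2^lfc_t * sstar
  comp_mult <- 1
  if (cf$competition_mode && n_t > 0) {
    rel_signal <- sum(mu_t_treated) / sum(mu_t)
    comp_mult <- 1 + cf$kappa * (1 - rel_signal)
  }
  mu_s_treated <- mu_s * sstar * comp_mult

  size <- 1 / cf$dispersion
  draw <- function(mu, k) {
    if (!length(mu)) return(matrix(numeric(0), 0, k))
    matrix(stats::rnbinom(length(mu) * k, mu = rep(mu, k), size = size),
           length(mu), k)
  }
  counts <- rbind(
    cbind(draw(mu_t, reps), draw(mu_t_treated, reps)),
    cbind(draw(mu_c, reps), draw(mu_c * sstar, reps)),
    cbind(draw(mu_s, reps), draw(mu_s_treated, reps))
  )
  sample_ids <- c(paste0("c", seq_len(reps)), paste0("t", seq_len(reps)))
  dimnames(counts) <- list(c(nm_t, nm_c, nm_s), sample_ids)
  totals <- cf$background_depth + colSums(counts)

  sheet <- sample_sheet(sample_ids,
                        condition = rep(c("control", "treated"), each = reps),
                        replicate = rep(seq_len(reps), 2))

  peaks <- synth_peak_layout(nm_t, nm_c, nm_s, cf$spikein_prefix)
  truth <- data.frame(
    name = c(nm_t, nm_c, nm_s),
    channel = rep(c("target", "control", "spike_in"), c(n_t, n_c, n_s)),
    true_log2fc = c(lfc_t, numeric(n_c), numeric(n_s)),
    mean = c(mu_t, mu_c, mu_s),
    stringsAsFactors = FALSE
  )
  list(counts = counts_matrix(counts, library_totals = totals),
       peaks = peaks,
       samples = sheet,
       truth = truth,
       channels = stats::setNames(truth$channel, truth$name))
}

# alternate target/control peaks (width 400, step 2000) over synthetic
# chromosomes of <= 25000 peaks each; spike-in on prefixed chromosomes
synth_peak_layout <- function(nm_t, nm_c, nm_s, spikein_prefix) {
  main_names <- character(0)
  main_channel <- character(0)
  i <- j <- 1L
  while (i <= length(nm_t) || j <= length(nm_c)) {
    if (i <= length(nm_t)) {
      main_names <- c(main_names, nm_t[i]); main_channel <- c(main_channel, "target")
      i <- i + 1L
    }
    if (j <= length(nm_c)) {
      main_names <- c(main_names, nm_c[j]); main_channel <- c(main_channel, "control")
      j <- j + 1L
    }
  }
  place <- function(names, chrom_prefix, per_chrom = 25000L) {
    n <- length(names)
    if (!n) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0)))
    }
    chrom_i <- (seq_len(n) - 1L) %/% per_chrom + 1L
    pos_i <- (seq_len(n) - 1L) %% per_chrom
    data.frame(chrom = paste0(chrom_prefix, "chr", chrom_i),
               start = pos_i * 2000L + 1000L,
               end = pos_i * 2000L + 1400L,
               name = names, stringsAsFactors = FALSE)
  }
  main <- place(main_names, "")
  spike <- place(nm_s, spikein_prefix)
  mk <- function(df, keep, channel, tag = "") {
    sel <- df[df$name %in% keep, , drop = FALSE]
    peak_set(sel$chrom, sel$start, sel$end, sel$name, score = 0,
             channel = channel, species_tag = tag)
  }
  list(target = mk(main, nm_t, "target"),
       control = mk(main, nm_c, "control"),
       spike_in = mk(spike, nm_s, "spike_in",
                     tag = sub("_$", "", spikein_prefix)))
}

#' Write a synthetic alignment fixture and count it back exactly
#'
#' Emits a coordinate-sorted, indexed BAM (via an intermediate SAM text
#' file) containing exactly the requested number of reads per peak, with
#' strand-aware 5' ends placed uniformly inside each peak, plus an optional
#' background of reads whose 5' ends avoid all peaks. Counting the fixture
#' with [count_reads_in_peaks()] returns the requested counts exactly, which
#' makes it the round-trip oracle for the counting rule. Reads wider than
#' their peak are clipped so the 5' end stays inside the peak.
#'
#' @param peaks a non-empty `refchip_peaks`.
#' @param read_counts non-negative integer vector, one per peak (recycled).
#' @param path output BAM path (`.bam`); the SAM text is kept alongside.
#' @param read_length read length in bp (default 50).
#' @param background number of background reads with 5' ends outside every
#'   peak (default 0).
#' @param mapq mapping quality written for every read (default 60).
#' @param seed RNG seed (mandatory).
#' @return Invisible list with elements `bam` and `sam`.
#' @export
generate_alignment_fixture <- function(peaks, read_counts, path,
                                       read_length = 50L, background = 0L,
                                       mapq = 60L, seed) {
  stopifnot(is_peak_set(peaks))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(read_counts < 0)) stop("read counts must be >= 0", call. = FALSE)
  read_counts <- rep_len(as.integer(read_counts), nrow(peaks))
  set.seed(seed)
  chrom_len <- tapply(peaks$end, peaks$chrom, max) + 10000L
  chroms <- names(chrom_len)

  recs <- list()
  for (i in seq_len(nrow(peaks))) {
    k <- read_counts[i]
    if (k == 0) next
    fp <- peaks$start[i] + sample.int(peaks$end[i] - peaks$start[i], k,
                                      replace = TRUE) - 1L
    recs[[length(recs) + 1L]] <-
      data.frame(chrom = peaks$chrom[i], fp = fp,
                 rev = stats::runif(k) < 0.5, stringsAsFactors = FALSE)
  }
  if (background > 0) {
    bg <- data.frame(chrom = character(0), fp = integer(0), rev = logical(0))
    gr_peaks <- peaks_to_granges(peaks)
    while (nrow(bg) < background) {
      need <- background - nrow(bg)
      cand_chrom <- sample(chroms, need, replace = TRUE)
      cand_fp <- floor(stats::runif(need) * (chrom_len[cand_chrom] - read_length))
      pts <- GenomicRanges::GRanges(cand_chrom,
                                    IRanges::IRanges(cand_fp + 1L, width = 1L))
      outside <- suppressWarnings(
        GenomicRanges::countOverlaps(pts, gr_peaks)) == 0
      bg <- rbind(bg, data.frame(chrom = cand_chrom[outside],
                                 fp = as.integer(cand_fp[outside]),
                                 rev = stats::runif(sum(outside)) < 0.5,
                                 stringsAsFactors = FALSE))
    }
    recs[[length(recs) + 1L]] <- bg[seq_len(background), , drop = FALSE]
  }
  reads <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(0), fp = integer(0), rev = logical(0))

  # leftmost 1-based position and effective length keeping the 5' end at fp
  len <- rep_len(as.integer(read_length), nrow(reads))
  pos0 <- ifelse(reads$rev, reads$fp - len + 1L, reads$fp)
  clip <- pmax(0L, -pos0)
  pos0 <- pos0 + clip
  len <- pmax(1L, len - clip)
  pos1 <- as.integer(pos0 + 1L)

  ord <- order(reads$chrom, pos1, method = "radix")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(chrom_len)))
  body <- if (nrow(reads)) {
    sprintf("read%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            seq_len(nrow(reads)),
            ifelse(reads$rev[ord], 16L, 0L),
            reads$chrom[ord], pos1[ord], as.integer(mapq), len[ord],
            strrep("A", len[ord]))
  } else character(0)
  sam <- sub("\\.bam$", ".sam", path)
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(list(bam = bam, sam = sam))
}
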