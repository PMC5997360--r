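# Seeded synthetic-data generators emulating the study design the analysis
# assumes: 18 sampling times per 24 h cycle (12:12 light:dark, three
# successive days collapsed to triplicates) and 15 kb promoter windows with
# planted motifs.  Every generator returns a truth manifest sufficient to
# regenerate its output bit-exactly.

#' The 18-point circadian sampling grid (hours after lights-on)
#'
#' Nine time points in the light period and nine in the dark period of a
#' 12:12 light:dark cycle; samples on successive days are treated as
#' triplicates.
#' @export
CIRCADIAN_GRID <- c(0.25, 1, 2, 4, 6, 8, 10, 11, 11.75,
                    12.25, 13, 14, 16, 18, 20, 22, 23, 23.75)

#' Light/dark annotation for times on the lights-on clock
#' @param time_h hours after lights-on.
#' @return `"light"` for times in `[0, 12)` (mod 24), else `"dark"`.
#' @export
light_phase <- function(time_h) {
  ifelse((time_h %% 24) < 12, "light", "dark")
}

#' Generate synthetic core-clock time-course data
#'
#' Simulates each tissue's model, normalizes every gene to cycle mean 1,
#' samples the 18-point grid, and applies multiplicative lognormal noise
#' calibrated so that the coefficient of variation equals `noise_cv`
#' (additive Gaussian available via `noise`).  The lognormal draw keeps
#' expression strictly positive.
#'
#' @param params_by_tissue named list: tissue -> `core_clock_params`.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param n_replicates replicates per time point (default 3).
#' @param seed integer seed; all randomness flows from it.
#' @param times sampling grid (hours after lights-on).
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @param burn_in,duration simulation layout (hours).
#' @param rel_tol,abs_tol,hmax integrator controls.
#' @return list: `data` (tissue, gene, time_h, replicate, value,
#'   phase_label), `manifest` (truth parameters, noise model, seed, and
#'   every argument needed to regenerate).
#' @export
generate_timecourse <- function(params_by_tissue, noise_cv = 0.1,
                                n_replicates = 3, seed = 1,
                                times = CIRCADIAN_GRID,
                                noise = c("lognormal", "gaussian"),
                                burn_in = 240, duration = 72,
                                rel_tol = 1e-6, abs_tol = 1e-9,
                                hmax = 0.25) {
  noise <- match.arg(noise)
  stopifnot(noise_cv >= 0, n_replicates >= 1)
  if (is.null(names(params_by_tissue)))
    stop("params_by_tissue must be a named list (tissue -> parameters)")
  set.seed(seed)
  warnings <- character(0)
  rows <- list()
  for (tissue in names(params_by_tissue)) {
    traj <- simulate_core_clock(params_by_tissue[[tissue]],
                                duration = duration, burn_in = burn_in,
                                rel_tol = rel_tol, abs_tol = abs_tol,
                                hmax = hmax)
    if (!traj$oscillation$sustained)
      warnings <- c(warnings, paste0("tissue ", tissue,
                                     ": oscillation not sustained"))
    prof <- tryCatch(model_profile(traj, times),
                     error = function(e) NULL)
    if (is.null(prof)) {
      # non-oscillatory truth: fall back to raw levels, data still produced
      prof <- dde_evaluate(traj, traj$window_start + times)
      warnings <- c(warnings, paste0("tissue ", tissue,
                                     ": period undefined, raw profile used"))
    }
    for (g in seq_along(CLOCK_GENES)) {
      clean <- rep(prof[, g], each = n_replicates)
      noisy <- apply_noise(clean, noise_cv, noise)
      rows[[paste(tissue, g)]] <- data.frame(
        tissue = tissue, gene = CLOCK_GENES[g],
        time_h = rep(times, each = n_replicates),
        replicate = rep(seq_len(n_replicates), length(times)),
        value = noisy, stringsAsFactors = FALSE)
    }
  }
  data <- canonical_order(do.call(rbind, c(rows, make.row.names = FALSE)))
  rownames(data) <- NULL
  data$phase_label <- light_phase(data$time_h)
  manifest <- list(
    kind = "timecourse",
    truth = lapply(params_by_tissue, function(p) unlist(p[PARAM_ORDER])),
    noise = noise, noise_cv = noise_cv, n_replicates = n_replicates,
    seed = seed, times = times, burn_in = burn_in, duration = duration,
    rel_tol = rel_tol, abs_tol = abs_tol, hmax = hmax,
    warnings = warnings)
  list(data = data, manifest = manifest)
}

apply_noise <- function(clean, cv, noise) {
  if (cv == 0) return(clean)
  if (noise == "lognormal") {
    sigma <- sqrt(log1p(cv^2))
    clean * rlnorm(length(clean), meanlog = -sigma^2 / 2, sdlog = sigma)
  } else {
    clean + rnorm(length(clean), sd = cv * abs(clean))
  }
}

#' Regenerate a time-course dataset from its truth manifest
#'
#' Bit-identical to the original generation.
#'
#' @param manifest manifest from [generate_timecourse()].
#' @return as [generate_timecourse()].
#' @export
regenerate_timecourse <- function(manifest) {
  stopifnot(identical(manifest$kind, "timecourse"))
  params <- lapply(manifest$truth, function(v)
    core_clock_parameters(base = v))
  generate_timecourse(params, noise_cv = manifest$noise_cv,
                      n_replicates = manifest$n_replicates,
                      seed = manifest$seed, times = manifest$times,
                      noise = manifest$noise, burn_in = manifest$burn_in,
                      duration = manifest$duration,
                      rel_tol = manifest$rel_tol,
                      abs_tol = manifest$abs_tol, hmax = manifest$hmax)
}

#' Generate synthetic CCG time-course data over core trajectories
#'
#' The default inter-tissue scenario: tissues share the consensus core
#' clock while CCG dissociation constants differ, the hypothesized
#' mechanism for inter-tissue phase variability.
#'
#' @param ccg_by_tissue named list: tissue -> `ccg_params`.
#' @param core_by_tissue named list: tissue -> core `dde_traj` (a single
#'   trajectory is recycled for all tissues).
#' @param noise_cv,n_replicates,seed,times,noise as
#'   [generate_timecourse()].
#' @return list: `data`, `manifest`.
#' @export
generate_ccg_timecourse <- function(ccg_by_tissue, core_by_tissue,
                                    noise_cv = 0.1, n_replicates = 3,
                                    seed = 1, times = CIRCADIAN_GRID,
                                    noise = c("lognormal", "gaussian")) {
  noise <- match.arg(noise)
  if (inherits(core_by_tissue, "dde_traj"))
    core_by_tissue <- setNames(
      rep(list(core_by_tissue), length(ccg_by_tissue)),
      names(ccg_by_tissue))
  set.seed(seed)
  rows <- list()
  for (tissue in names(ccg_by_tissue)) {
    core <- core_by_tissue[[tissue]]
    ccg <- ccg_by_tissue[[tissue]]
    period <- estimate_period(core)
    traj <- simulate_ccg(ccg, core)
    prof <- model_profile(traj, times, period = period)
    clean <- rep(prof[, 1], each = n_replicates)
    rows[[tissue]] <- data.frame(
      tissue = tissue, gene = ccg$gene,
      time_h = rep(times, each = n_replicates),
      replicate = rep(seq_len(n_replicates), length(times)),
      value = apply_noise(clean, noise_cv, noise),
      stringsAsFactors = FALSE)
  }
  data <- canonical_order(do.call(rbind, c(rows, make.row.names = FALSE)))
  rownames(data) <- NULL
  data$phase_label <- light_phase(data$time_h)
  manifest <- list(kind = "ccg_timecourse",
                   truth = lapply(ccg_by_tissue, unclass),
                   noise = noise, noise_cv = noise_cv,
                   n_replicates = n_replicates, seed = seed, times = times)
  list(data = data, manifest = manifest)
}

#' Generate promoter sequences with planted consensus motifs
#'
#' I.i.d. background at the stated GC content with consensus motifs
#' planted at recorded non-overlapping positions on random strands.
#'
#' @param plan data.frame with columns `gene`, `k_ebox`, `k_rre`,
#'   `k_dbox` (non-negative planting counts).
#' @param length sequence length (default 15000, the -10 kb/+5 kb window).
#' @param gc GC content of the background (default 0.42).
#' @param seed integer seed.
#' @param pwms list with `ebox`, `rre`, `dbox` `pwm` objects whose
#'   consensus sequences are planted (default [example_pwms()]).
#' @return list: `sequences` (named character vector), `manifest`
#'   (plantings with gene, motif class, position, strand; plus all
#'   arguments).
#' @export
generate_promoters <- function(plan, length = 15000, gc = 0.42, seed = 1,
                               pwms = example_pwms()) {
  need <- c("gene", "k_ebox", "k_rre", "k_dbox")
  if (!all(need %in% names(plan)))
    stop("plan needs columns: ", paste(need, collapse = ", "))
  ks <- as.matrix(plan[, c("k_ebox", "k_rre", "k_dbox")])
  if (any(ks < 0) || any(ks != round(ks)))
    stop("planting counts must be non-negative integers")
  set.seed(seed)
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  classes <- c("ebox", "rre", "dbox")
  seqs <- character(nrow(plan))
  plant_rows <- list()
  for (i in seq_len(nrow(plan))) {
    gene <- as.character(plan$gene[i])
    chars <- sample(DNA_BASES, length, replace = TRUE, prob = base_probs)
    motifs <- rep(classes, times = ks[i, ])
    lens <- vapply(motifs, function(m) pwms[[m]]$length, integer(1))
    if (sum(lens + 1) > length)
      stop("planting plan infeasible for sequence length ", length)
    occupied <- rep(FALSE, length)
    for (j in seq_along(motifs)) {
      m <- motifs[j]
      L <- pwms[[m]]$length
      # rejection-sample a non-overlapping start
      for (try in 1:10000) {
        pos <- sample.int(length - L + 1L, 1L)
        if (!any(occupied[pos:(pos + L - 1L)])) break
        if (try == 10000) stop("could not place motif without overlap")
      }
      occupied[pos:(pos + L - 1L)] <- TRUE
      strand <- sample(c("+", "-"), 1L)
      cons <- pwms[[m]]$consensus
      if (strand == "-") cons <- revcomp(cons)
      chars[pos:(pos + L - 1L)] <- strsplit(cons, "")[[1]]
      plant_rows[[paste(i, j)]] <- data.frame(
        gene = gene, class = m, motif = pwms[[m]]$id, start = pos,
        end = pos + L - 1L, strand = strand, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  names(seqs) <- as.character(plan$gene)
  plantings <- if (length(plant_rows))
    do.call(rbind, c(plant_rows, make.row.names = FALSE)) else
      data.frame(gene = character(0), class = character(0),
                 motif = character(0), start = integer(0),
                 end = integer(0), strand = character(0))
  manifest <- list(kind = "promoters", plan = plan, length = length,
                   gc = gc, seed = seed, plantings = plantings,
                   pwm_ids = vapply(pwms, function(p) p$id, character(1)))
  list(sequences = seqs, manifest = manifest)
}

#' Write promoter sequences as FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
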