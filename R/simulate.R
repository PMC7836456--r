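# Seeded synthetic-data generator emulating the statistical structure of an
# isoform-specific CRISPRi dropout screen: toy genome with promoter pairs,
# tumour/normal H3K4me3 matrices with planted gains, a designed library and
# negative-binomial screen counts with planted isoform-specific
# essentiality. Every pipeline stage is testable against the planted truth.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 17 tumour/normal signal pairs,
#' 1000x guide coverage, two day-21 replicates per cell line, 5 cancer lines
#' plus one normal line, 6 guides per promoter in a +/-150 bp TSS window.
#'
#' @param seed Integer seed driving every stage.
#' @param n_genes Number of simulated genes (excluding control genes).
#' @param prob_two_promoters Probability a gene carries a second, unaltered
#'   promoter.
#' @param n_pairs Tumour/normal H3K4me3 sample pairs (default 17).
#' @param gain_fraction Fraction of genes whose primary promoter is gained
#'   (an equal fraction is lost).
#' @param gain_log2fc Planted tumour/normal log2 effect (default 2).
#' @param signal_noise_sd SD of multiplicative log-normal signal noise,
#'   `exp(N(0, sd))` (default 0.25).
#' @param fraction_expressed Probability a gained/lost isoform is expressed
#'   (FPKM >= 5).
#' @param n_cell_lines Number of cancer cell lines (default 5).
#' @param normal_line Include a non-transformed control line (default TRUE).
#' @param coverage Mean DNA-pool reads per guide (default 1000).
#' @param nb_dispersion Negative-binomial dispersion of counts (default
#'   0.05).
#' @param essential_fraction Fraction of gained, expressed isoforms planted
#'   as cancer dependencies.
#' @param essential_log2fc Day-21 depletion effect of essential guides
#'   (default -2, i.e. 4-fold dropout).
#' @param n_essential_genes Core-essential positive-control genes (lethal in
#'   every line).
#' @param n_negative Negative-control guides.
#' @param bidirectional_decoys Non-essential promoters planted < 2000 bp
#'   from a pan-essential TSS that score through off-target silencing.
#' @param window,guides_per_promoter Library design parameters.
#' @param spacing Minimum distance between unrelated promoters in bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 60, prob_two_promoters = 0.7,
                       n_pairs = 17, gain_fraction = 0.25, gain_log2fc = 2,
                       signal_noise_sd = 0.25, fraction_expressed = 0.8,
                       n_cell_lines = 5, normal_line = TRUE, coverage = 1000,
                       nb_dispersion = 0.05, essential_fraction = 0.3,
                       essential_log2fc = -2, n_essential_genes = 10,
                       n_negative = 100, bidirectional_decoys = 1,
                       window = 150, guides_per_promoter = 6,
                       spacing = 5000) {
  cfg <- as.list(environment())
  fr <- c("gain_fraction", "fraction_expressed", "essential_fraction",
          "prob_two_promoters")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must be in [0, 1]")
  if (coverage <= 0) stop("coverage must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (2 * gain_fraction > 1) stop("gain_fraction too large: gained and lost sets overlap")
  if (spacing < 4 * (window + 50)) stop("spacing too small for the design window")
  class(cfg) <- "sim_config"
  cfg
}

sim_lines <- function(config) paste0("GC", seq_len(config$n_cell_lines))

#' Simulate a toy genome, promoter annotation and planted truth
#'
#' Lays promoters out along one random chromosome at least `spacing` bp
#' apart, except bidirectional decoys, which are placed 600-1800 bp from a
#' pan-essential control TSS. Each promoter window is guaranteed to contain
#' at least 10 PAM-adjacent, genome-unique candidate spacers (windows are
#' resampled until this holds). Gained/lost status, expression, planted
#' per-line essentiality and decoy roles are assigned here, honouring the
#' premise that a dependency can only act through an expressed isoform.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (DNAStringSet), `promoters` (annotation
#'   data.frame) and `truth` (one row per promoter: `planted_status`,
#'   `expressed`, `fpkm`, `planted_effect`, `essential_in` comma-separated
#'   line names, `decoy_role`).
#' @export
make_genome_and_promoters <- function(config) {
  set.seed(config$seed)
  lines <- sim_lines(config)
  all_lines <- c(lines, if (config$normal_line) "NORM")

  two <- stats::runif(config$n_genes) < config$prob_two_promoters
  gene <- sprintf("gene%03d", seq_len(config$n_genes))
  prom <- data.frame(
    promoter_id = c(paste0(gene, "_P1"),
                    if (any(two)) paste0(gene[two], "_P2"),
                    sprintf("ess%02d_P1", seq_len(config$n_essential_genes)),
                    if (config$bidirectional_decoys > 0)
                      sprintf("decoy%02d_P1",
                              seq_len(config$bidirectional_decoys))),
    gene_id = c(gene, gene[two],
                sprintf("ESS%02d", seq_len(config$n_essential_genes)),
                if (config$bidirectional_decoys > 0)
                  sprintf("DECOY%02d",
                          seq_len(config$bidirectional_decoys))),
    stringsAsFactors = FALSE)
  prom$label <- sub("^.*_", "", prom$promoter_id)
  role <- rep("gene", nrow(prom))
  role[grepl("^ess", prom$promoter_id)] <- "essential_control"
  role[grepl("^decoy", prom$promoter_id)] <- "decoy"
  if (config$bidirectional_decoys > config$n_essential_genes)
    stop("more decoys than pan-essential TSSs to pair them with")

  # layout: non-decoy promoters spaced >= spacing apart with jitter; each
  # decoy sits 600-1800 bp from a distinct essential-control TSS
  main <- which(role != "decoy")
  pos <- integer(nrow(prom))
  cur <- config$spacing
  for (i in main) {
    pos[i] <- cur + sample.int(500L, 1L)
    cur <- pos[i] + config$spacing
  }
  ess_idx <- which(role == "essential_control")
  dec_idx <- which(role == "decoy")
  for (k in seq_along(dec_idx)) {
    d <- sample(600:1800, 1L)
    pos[dec_idx[k]] <- pos[ess_idx[k]] + d
  }
  prom$chrom <- "chrS"
  prom$tss <- pos
  prom$strand <- sample(c("+", "-"), nrow(prom), replace = TRUE)
  glen <- max(pos) + config$spacing
  gchar <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                 collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(gchar, "chrS"))

  # guarantee >= 10 unique PAM-adjacent candidates in every design window;
  # check all windows in one batched uniqueness pass, then patch stragglers
  n_unique_candidates <- function(idx) {
    cand <- do.call(rbind, lapply(idx, function(i) {
      x <- enumerate_candidates(genome, prom[i, , drop = FALSE],
                                config$window)
      x[!grepl("TTTT", x$spacer, fixed = TRUE), , drop = FALSE]
    }))
    hits <- count_genome_matches_many(cand$spacer, genome)
    cnt <- table(factor(cand$target_promoter_id[hits == 1L],
                        levels = prom$promoter_id[idx]))
    as.integer(cnt)
  }
  short <- which(n_unique_candidates(seq_len(nrow(prom))) < 10L)
  for (i in short) {
    for (try in 1:20) {
      if (n_unique_candidates(i) >= 10L) break
      if (try == 20L) stop("could not seed candidates near ",
                           prom$promoter_id[i])
      lo <- max(1L, prom$tss[i] - config$window - 25L)
      hi <- min(glen, prom$tss[i] + config$window + 25L)
      substr(gchar, lo, hi) <- paste(
        sample(c("A", "C", "G", "T"), hi - lo + 1L, replace = TRUE),
        collapse = "")
      genome <- Biostrings::DNAStringSet(stats::setNames(gchar, "chrS"))
    }
  }

  # planted truth
  n_gain <- round(config$gain_fraction * config$n_genes)
  shuffled <- sample(gene)
  gained_genes <- shuffled[seq_len(n_gain)]
  lost_genes <- shuffled[n_gain + seq_len(n_gain)]
  status <- rep("unaltered", nrow(prom))
  p1 <- prom$label == "P1" & role == "gene"
  status[p1 & prom$gene_id %in% gained_genes] <- "gained"
  status[p1 & prom$gene_id %in% lost_genes] <- "lost"
  status[role == "decoy"] <- "gained"

  expressed <- rep(FALSE, nrow(prom))
  altered <- status != "unaltered" & role == "gene"
  expressed[altered] <- stats::runif(sum(altered)) < config$fraction_expressed
  unalt_p2 <- prom$label == "P2" & role == "gene"
  expressed[unalt_p2] <- stats::runif(sum(unalt_p2)) < 0.3
  expressed[role %in% c("essential_control", "decoy")] <- TRUE

  fpkm <- numeric(nrow(prom))
  fpkm[expressed] <- 5 + stats::rlnorm(sum(expressed), 2.5, 0.8)
  fpkm[!expressed] <- stats::runif(sum(!expressed), 0, 2)

  essential_in <- rep("", nrow(prom))
  eligible <- which(status == "gained" & expressed & role == "gene")
  n_ess <- round(config$essential_fraction * length(eligible))
  planted <- sample(eligible, n_ess)
  for (i in planted) {
    k <- sample.int(config$n_cell_lines, 1L)
    essential_in[i] <- paste(sort(sample(lines, k)), collapse = ",")
  }
  essential_in[role %in% c("essential_control", "decoy")] <-
    paste(all_lines, collapse = ",")

  effect <- ifelse(nzchar(essential_in), config$essential_log2fc, 0)
  truth <- data.frame(
    promoter_id = prom$promoter_id, gene_id = prom$gene_id,
    planted_status = status, expressed = expressed, fpkm = fpkm,
    planted_effect = effect, essential_in = essential_in,
    decoy_role = ifelse(role == "decoy", "bidirectional_pan_essential",
                        "none"),
    role = role, stringsAsFactors = FALSE)
  list(genome = genome,
       promoters = prom[, c("promoter_id", "gene_id", "label", "chrom",
                            "tss", "strand")],
       truth = truth)
}

#' Simulate paired tumour/normal H3K4me3 signals
#'
#' Baseline signals are log-normal (meanlog 3, sdlog 0.5) per promoter and
#' pair; gained promoters get their tumour signal multiplied by
#' `2^gain_log2fc` in a random subset of 2 to `n_pairs` pairs (lost
#' promoters symmetrically on the normal side); both channels then receive
#' independent multiplicative noise `exp(N(0, signal_noise_sd))`. Signals
#' are always non-negative.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [make_genome_and_promoters()].
#' @return Long signal data.frame: `promoter_id`, `sample_id`, `tumour`,
#'   `normal`.
#' @export
make_h3k4me3 <- function(config, truth) {
  set.seed(config$seed + 1L)
  np <- config$n_pairs
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    base <- stats::rlnorm(np, 3, 0.5)
    eff <- numeric(np)
    st <- truth$planted_status[i]
    if (st != "unaltered") {
      k <- sample(2:np, 1L)
      sel <- sample.int(np, k)
      eff[sel] <- if (st == "gained") config$gain_log2fc else -config$gain_log2fc
    }
    tum <- base * 2^pmax(eff, 0) * exp(stats::rnorm(np, 0, config$signal_noise_sd))
    nor <- base * 2^(-pmin(eff, 0)) * exp(stats::rnorm(np, 0, config$signal_noise_sd))
    data.frame(promoter_id = truth$promoter_id[i],
               sample_id = sprintf("pair%02d", seq_len(np)),
               tumour = tum, normal = nor, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Skeleton guide library without sequence design
#'
#' Builds a minimal library table (guide IDs, targets, categories, no
#' spacers) for counts-level benchmarks where the genome is irrelevant.
#'
#' @param promoter_ids Targeted promoter IDs (one gene per promoter).
#' @param guides_per_promoter Guides per promoter (default 6).
#' @param n_negative Negative-control guides (default 0).
#' @return A guide library data.frame usable by [make_screen_counts()] and
#'   [score_transcripts()].
#' @export
sim_screen_library <- function(promoter_ids, guides_per_promoter = 6,
                               n_negative = 0) {
  tgt <- data.frame(
    guide_id = paste0(rep(promoter_ids, each = guides_per_promoter), "_sg",
                      seq_len(guides_per_promoter)),
    spacer = NA_character_,
    target_promoter_id = rep(promoter_ids, each = guides_per_promoter),
    gene_id = rep(sub("_P[0-9]+$", "", promoter_ids),
                  each = guides_per_promoter),
    category = "targeting", stringsAsFactors = FALSE)
  if (n_negative > 0)
    tgt <- rbind(tgt, data.frame(
      guide_id = sprintf("neg_%04d", seq_len(n_negative)),
      spacer = NA_character_, target_promoter_id = NA_character_,
      gene_id = NA_character_, category = "negative_control",
      stringsAsFactors = FALSE))
  tgt
}

#' Simulate pooled-screen counts for every cell line
#'
#' DNA-pool counts are negative binomial with mean `coverage` and dispersion
#' `nb_dispersion`; each of two day-21 replicates has mean
#' `coverage * 2^effect`, where a guide's effect is the promoter's planted
#' effect when the promoter is expressed and essential in that line, and 0
#' otherwise — so guides on the unexpressed isoform of an essential gene
#' behave exactly like negative controls.
#'
#' @param library Guide library ([build_library()] or
#'   [sim_screen_library()]).
#' @param truth Truth table with `promoter_id`, `expressed`,
#'   `planted_effect`, `essential_in`.
#' @param config A [sim_config()].
#' @return Named list (one per cell line, plus "NORM" when configured) of
#'   integer count matrices with columns `pool`, `d21_r1`, `d21_r2`.
#' @export
make_screen_counts <- function(library, truth, config) {
  set.seed(config$seed + 2L)
  tgt <- library$target_promoter_id
  unknown <- setdiff(stats::na.omit(tgt), truth$promoter_id)
  if (length(unknown))
    stop("library targets absent from truth: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  ti <- match(tgt, truth$promoter_id)
  ess_lines <- strsplit(truth$essential_in, ",", fixed = TRUE)
  lines <- c(sim_lines(config), if (config$normal_line) "NORM")
  size <- 1 / config$nb_dispersion
  ng <- nrow(library)
  out <- list()
  for (ln in lines) {
    eff <- numeric(ng)
    hit <- !is.na(ti) & truth$expressed[ifelse(is.na(ti), 1L, ti)] &
      vapply(seq_len(ng), function(g)
        !is.na(ti[g]) && ln %in% ess_lines[[ti[g]]], TRUE)
    eff[hit] <- truth$planted_effect[ti[hit]]
    m <- cbind(
      pool = stats::rnbinom(ng, mu = config$coverage, size = size),
      d21_r1 = stats::rnbinom(ng, mu = config$coverage * 2^eff, size = size),
      d21_r2 = stats::rnbinom(ng, mu = config$coverage * 2^eff, size = size))
    rownames(m) <- library$guide_id
    storage.mode(m) <- "integer"
    out[[ln]] <- m
  }
  out
}

#' Run the whole pipeline on one simulation
#'
#' Generates genome, signals and screen; runs promoter calling, library
#' design, LFC scoring, alpha-RRA and hit filtering; and compares the result
#' with the planted truth.
#'
#' @param config A [sim_config()].
#' @param alpha,n_perm,fdr_cutoff,min_lines Analysis parameters.
#' @return A list with all intermediate artifacts and a `report` list of
#'   metrics: `promoter_call_recall`, `promoter_call_precision`,
#'   `false_gain_rate`, `hit_sensitivity`, `observed_fdr`,
#'   `decoy_removed`, plus the filter cascade counts.
#' @export
simulate_screen <- function(config = sim_config(), alpha = 0.25,
                            n_perm = 1000, fdr_cutoff = 0.1, min_lines = 2) {
  gen <- make_genome_and_promoters(config)
  truth <- gen$truth
  signals <- make_h3k4me3(config, truth)
  calls <- call_promoters(signals, gen$promoters)
  calls <- select_screen_targets(
    calls, data.frame(promoter_id = truth$promoter_id, fpkm = truth$fpkm))

  ti <- match(calls$promoter_id, truth$promoter_id)
  planted_alt <- truth$planted_status[ti] != "unaltered" &
    truth$role[ti] == "gene"
  called_match <- calls$status == truth$planted_status[ti]
  promoter_recall <- mean(called_match[planted_alt])
  called_alt <- calls$status != "unaltered" & truth$role[ti] == "gene"
  promoter_precision <- if (any(called_alt))
    mean(called_match[called_alt]) else NA_real_
  null_prom <- truth$planted_status[ti] == "unaltered" &
    truth$role[ti] == "gene"
  false_gain_rate <- mean(calls$status[null_prom] == "gained")

  ess_ids <- truth$promoter_id[truth$role == "essential_control"]
  selected_ids <- setdiff(calls$promoter_id[calls$selected], ess_ids)
  library <- build_library(gen$genome, gen$promoters, selected_ids,
                           essential_ids = ess_ids,
                           n_negative = config$n_negative,
                           window = config$window,
                           guides_per_promoter = config$guides_per_promoter)

  counts <- make_screen_counts(library, truth, config)
  scores <- list()
  for (i in seq_along(counts)) {
    lfc <- guide_lfc(counts[[i]], reference = "pool")
    scores[[names(counts)[i]]] <- score_transcripts(
      lfc, library, alpha = alpha, n_perm = n_perm,
      fdr_cutoff = fdr_cutoff, seed = config$seed + 100L + i)
  }
  pan_list <- unique(truth$gene_id[truth$role == "essential_control"])
  normal <- if (config$normal_line) "NORM" else NULL
  hits <- intersect_lines(scores, fdr_cutoff = fdr_cutoff,
                          min_lines = min_lines, normal = normal,
                          pan_list = pan_list)
  hits <- bidirectional_filter(hits, gen$promoters, max_distance = 2000,
                               pan_list = pan_list)
  hits <- contrast_normal(hits, if (!is.null(normal)) scores[[normal]],
                          fdr_cutoff)

  n_lines_planted <- vapply(strsplit(truth$essential_in, ",", fixed = TRUE),
                            function(x) sum(x %in% sim_lines(config)), 0L)
  planted_gc <- truth$promoter_id[
    n_lines_planted >= min_lines & truth$decoy_role == "none" &
      truth$role == "gene"]
  final <- hits$promoter_id[hits$final_hit]
  hit_sensitivity <- if (length(planted_gc))
    mean(planted_gc %in% final) else NA_real_
  observed_fdr <- if (length(final))
    mean(!final %in% planted_gc) else NA_real_
  decoys <- truth$promoter_id[truth$decoy_role != "none"]
  decoy_removed <- !any(decoys %in% final)

  report <- list(promoter_call_recall = promoter_recall,
                 promoter_call_precision = promoter_precision,
                 false_gain_rate = false_gain_rate,
                 hit_sensitivity = hit_sensitivity,
                 observed_fdr = observed_fdr,
                 decoy_removed = decoy_removed,
                 cascade = as.list(hit_cascade(hits, min_lines)))
  list(genome = gen$genome, promoters = gen$promoters, truth = truth,
       signals = signals, calls = calls, library = library, counts = counts,
       scores = scores, hits = hits, report = report)
}

#' End-to-end benchmark report
#'
#' Convenience wrapper around [simulate_screen()] returning only the
#' machine-readable metrics report.
#'
#' @inheritParams simulate_screen
#' @return The `report` list (JSON-serialisable).
#' @export
end_to_end_benchmark <- function(config = sim_config(), alpha = 0.25,
                                 n_perm = 1000, fdr_cutoff = 0.1,
                                 min_lines = 2) {
  simulate_screen(config, alpha, n_perm, fdr_cutoff, min_lines)$report
}
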