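# Programmatic fixtures shared across test files. Everything is generated
# in code; no data files are read from disk.

# An A/T-only background sequence: contains no G or C, hence no PAM on
# either strand until one is planted.
at_background <- function(n, seed = 42) {
  withr::with_seed(seed,
    paste(sample(c("A", "T"), n, replace = TRUE), collapse = ""))
}

# Plant a plus-strand protospacer+PAM so the guide anchor (PAM-proximal
# base) sits at 0-based position `anchor0`; returns the modified sequence
# and the planted spacer.
plant_plus_site <- function(seqchar, anchor0, seed = 7) {
  # A/T-only spacer so no stray PAM (GG/CC) is created by the insertion
  spacer <- withr::with_seed(seed,
    paste(sample(c("A", "T"), 20, replace = TRUE), collapse = ""))
  s1 <- anchor0 + 1L - 19L               # 1-based spacer start
  substr(seqchar, s1, s1 + 19L) <- spacer
  substr(seqchar, s1 + 20L, s1 + 22L) <- "TGG"
  list(seq = seqchar, spacer = spacer)
}

as_genome <- function(seqchar, name = "chrT") {
  Biostrings::DNAStringSet(stats::setNames(seqchar, name))
}

one_promoter <- function(tss0, strand = "+", chrom = "chrT",
                         promoter_id = "pTest_P1", gene_id = "pTest") {
  data.frame(promoter_id = promoter_id, gene_id = gene_id, label = "P1",
             chrom = chrom, tss = as.integer(tss0), strand = strand,
             stringsAsFactors = FALSE)
}

random_genome <- function(n, seed, name = "chrR") {
  withr::with_seed(seed, as_genome(
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    name))
}

# Counts-level screen fixture: a skeleton library, a truth table with
# planted essential promoters, and one cell line's simulated counts.
spikein_fixture <- function(n_promoters, n_essential, seed,
                            coverage = 500, dispersion = 0.05,
                            effect = -2, n_negative = 1000,
                            guides_per_promoter = 6) {
  prom <- sprintf("prom%04d_P1", seq_len(n_promoters))
  lib <- isoscreen::sim_screen_library(prom, guides_per_promoter, n_negative)
  truth <- data.frame(
    promoter_id = prom, gene_id = sub("_P1$", "", prom),
    expressed = TRUE,
    planted_effect = c(rep(effect, n_essential),
                       rep(0, n_promoters - n_essential)),
    essential_in = c(rep("GC1", n_essential),
                     rep("", n_promoters - n_essential)),
    stringsAsFactors = FALSE)
  cfg <- isoscreen::sim_config(seed = seed, n_cell_lines = 1,
                               normal_line = FALSE, coverage = coverage,
                               nb_dispersion = dispersion,
                               essential_log2fc = effect)
  counts <- isoscreen::make_screen_counts(lib, truth, cfg)[["GC1"]]
  list(library = lib, truth = truth, counts = counts,
       planted = prom[seq_len(n_essential)])
}

# Score one cell line's counts end to end (lfc + alpha-RRA).
score_fixture <- function(fx, n_perm = 1000, seed = 1, fdr_cutoff = 0.1) {
  lfc <- isoscreen::guide_lfc(fx$counts, reference = "pool")
  isoscreen::score_transcripts(lfc, fx$library, n_perm = n_perm, seed = seed,
                               fdr_cutoff = fdr_cutoff)
}

# Minimal per-line score table for filter tests.
mk_scores <- function(promoter_id, fdr, gene_id = sub("_P[0-9]+$", "",
                                                      promoter_id)) {
  data.frame(promoter_id = promoter_id, gene_id = gene_id,
             n_guides = 6L, n_obs = 6L, rho = fdr, p_value = fdr, fdr = fdr,
             essential = fdr <= 0.1, direction = "depletion",
             stringsAsFactors = FALSE)
}
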