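# Transcript-level negative-selection scoring by alpha-robust-rank
# aggregation (alpha-RRA) with a permutation null and Benjamini-Hochberg
# FDR.

#' The alpha-RRA rho statistic
#'
#' Given a guide set's normalised ranks `r(1) <= ... <= r(n)` in (0, 1],
#' computes for every j whose rank satisfies `r(j) <= alpha` the binomial
#' tail probability `p_j = Pr[Binomial(n, r(j)) >= j]` — the probability
#' that at least j of n uniform ranks fall at or below r(j) — and returns
#' the minimum. If no rank is below alpha, rho is 1. Small rho means the
#' set's top ranks are improbably concentrated near the head of the list.
#'
#' @param norm_ranks Numeric vector of normalised ranks in (0, 1].
#' @param alpha Fraction of the ranked list considered relevant (default
#'   0.25).
#' @return rho in (0, 1].
#' @export
rho_statistic <- function(norm_ranks, alpha = 0.25) {
  if (length(norm_ranks) == 0L) stop("empty rank vector")
  if (any(norm_ranks <= 0 | norm_ranks > 1))
    stop("normalised ranks must lie in (0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  r <- sort(norm_ranks)
  n <- length(r)
  elig <- which(r <= alpha)
  if (!length(elig)) return(1)
  p <- stats::pbinom(elig - 1L, n, r[elig], lower.tail = FALSE)
  min(p)
}

#' Empirical null distribution of rho
#'
#' Draws `n_perm` guide sets of size `n_obs` by sampling ranks uniformly
#' without replacement from `{1..G}/G` and computes rho for each, giving the
#' permutation null used for p-values. Uses the current RNG state.
#'
#' @param n_obs Number of rank observations per set (guides x replicate
#'   samples).
#' @param G Total number of guides in the ranked list.
#' @param alpha See [rho_statistic()].
#' @param n_perm Number of permutations (>= 100 recommended).
#' @return Numeric vector of `n_perm` null rho values.
#' @export
permutation_null <- function(n_obs, G, alpha = 0.25, n_perm = 1000) {
  if (n_obs > G) stop("n_obs exceeds total number of guides G")
  if (n_perm < 1) stop("n_perm must be >= 1")
  R <- vapply(seq_len(n_perm),
              function(i) sort(sample.int(G, n_obs)) / G,
              numeric(n_obs))
  R <- matrix(R, nrow = n_obs)  # n_obs x n_perm
  P <- stats::pbinom(rep(seq_len(n_obs) - 1L, n_perm), n_obs, as.vector(R),
                     lower.tail = FALSE)
  P <- matrix(P, nrow = n_obs)
  P[R > alpha] <- 1  # ineligible ranks never set the minimum; all-masked -> 1
  apply(P, 2L, min)
}

#' Score transcript isoforms by alpha-RRA with a permutation FDR
#'
#' Aggregates each promoter's guide ranks (all replicate samples
#' concatenated) into a rho statistic, estimates a p-value against a
#' size-matched permutation null with the add-one estimator
#' `p = (1 + #{null rho <= observed}) / (n_perm + 1)`, and applies
#' Benjamini-Hochberg correction across promoters. For depletion scoring,
#' ranks ascend with log2 fold change so dropout guides rank first; for
#' enrichment the ranking is reversed.
#'
#' @param lfc Guide score table from [guide_lfc()] (all replicate samples of
#'   one cell line).
#' @param library Guide library data.frame mapping `guide_id` to
#'   `target_promoter_id`, `gene_id` and `category`.
#' @param alpha,n_perm See [rho_statistic()] and [permutation_null()].
#' @param fdr_cutoff Essentiality call threshold on the BH FDR (default
#'   0.1).
#' @param seed Optional integer seed for the permutation null.
#' @param direction "depletion" (default) or "enrichment".
#' @return A data.frame with one row per scored promoter: `promoter_id`,
#'   `gene_id`, `n_guides`, `n_obs`, `rho`, `p_value`, `fdr`, `essential`,
#'   `direction`.
#' @export
score_transcripts <- function(lfc, library, alpha = 0.25, n_perm = 1000,
                              fdr_cutoff = 0.1, seed = NULL,
                              direction = c("depletion", "enrichment")) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  G <- length(unique(lfc$guide_id))
  tgt <- library[!is.na(library$target_promoter_id), , drop = FALSE]
  lost <- setdiff(tgt$guide_id, lfc$guide_id)
  if (length(lost))
    warning(length(lost), " library guide(s) absent from the lfc table")
  obs <- lfc[lfc$guide_id %in% tgt$guide_id, , drop = FALSE]
  obs$promoter_id <- tgt$target_promoter_id[match(obs$guide_id, tgt$guide_id)]
  nr <- if (direction == "depletion") obs$norm_rank
        else 1 + 1 / G - obs$norm_rank
  ranks_by_prom <- split(nr, obs$promoter_id)
  guides_by_prom <- split(obs$guide_id, obs$promoter_id)
  null_cache <- new.env(parent = emptyenv())
  prom <- names(ranks_by_prom)
  res <- lapply(prom, function(p) {
    r <- ranks_by_prom[[p]]
    n_obs <- length(r)
    rho <- rho_statistic(r, alpha)
    key <- as.character(n_obs)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- permutation_null(n_obs, G, alpha, n_perm)
    null <- null_cache[[key]]
    pval <- (1 + sum(null <= rho)) / (n_perm + 1)
    data.frame(promoter_id = p,
               n_guides = length(unique(guides_by_prom[[p]])),
               n_obs = n_obs, rho = rho, p_value = pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$gene_id <- tgt$gene_id[match(out$promoter_id, tgt$target_promoter_id)]
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$essential <- out$fdr <= fdr_cutoff
  out$direction <- direction
  out <- out[order(out$p_value, out$promoter_id),
             c("promoter_id", "gene_id", "n_guides", "n_obs", "rho",
               "p_value", "fdr", "essential", "direction")]
  rownames(out) <- NULL
  out
}
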