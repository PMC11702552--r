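#' Default analysis thresholds and parameters
#'
#' Returns the pipeline-wide default configuration: the promoter window,
#' significance thresholds, permutation and sampling counts, and window
#' sizes used by the rhythmicity, DDR, and enrichment stages. These are
#' the study's operating values; individual functions accept overrides.
#'
#' @return Named list of defaults:
#' \describe{
#'   \item{promoter_upstream, promoter_downstream}{promoter window around
#'     the TSS, in bp (1000 and 500).}
#'   \item{period_h}{diel period in hours (24).}
#'   \item{cycling_alpha}{per-gene rhythmicity LR test threshold (0.01).}
#'   \item{kw_alpha}{DDR candidacy threshold on the KW permutation
#'     p-value (0.05).}
#'   \item{min_cycling, min_expressed}{minimum numbers of inbreds that
#'     must cycle / be expressed for DDR candidacy (6 and 6).}
#'   \item{expr_floor}{baseline normalized-abundance floor defining
#'     "expressed" (50).}
#'   \item{n_perm_kw}{KW haplotype-label permutations (10000).}
#'   \item{confirm_alpha}{amplitude-difference confirmation threshold
#'     (0.01).}
#'   \item{gene_flank_bp}{flank added to gene spans for SNP overlap
#'     (1000).}
#'   \item{n_null_samples}{null gene-set samples for enrichment tests
#'     (1000).}
#'   \item{cis_window_bp}{cis-eQTL window around the focal gene (5000).}
#'   \item{gwas_hit_p}{GWAS hit definition (1e-5).}
#'   \item{n_matched_draws}{matched SNP draws for the eQTL overlap test
#'     (10000).}
#'   \item{fst_top_k}{Fst SNPs kept as putative adaptation variants
#'     (10000).}
#' }
#' @export
diel_defaults <- function() {
  list(
    promoter_upstream   = 1000L,
    promoter_downstream = 500L,
    period_h            = 24,
    cycling_alpha       = 0.01,
    kw_alpha            = 0.05,
    min_cycling         = 6L,
    min_expressed       = 6L,
    expr_floor          = 50,
    n_perm_kw           = 10000L,
    confirm_alpha       = 0.01,
    gene_flank_bp       = 1000L,
    n_null_samples      = 1000L,
    cis_window_bp       = 5000L,
    gwas_hit_p          = 1e-5,
    n_matched_draws     = 10000L,
    fst_top_k           = 10000L
  )
}
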