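# Instrument-set construction: genome-wide lipid panels and cis
# gene-region (drug-target) selections with greedy LD pruning.

.LIPIDS <- c("ldl", "hdl", "tg")

.panel_cols <- function(lipid) {
  c(beta = paste0("beta_", lipid), se = paste0("se_", lipid),
    p = paste0("p_", lipid))
}

.check_panel <- function(panel, lipids = .LIPIDS) {
  need <- c("rsid", as.vector(vapply(lipids, .panel_cols, character(3))))
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0)
    stop("lipid panel missing column(s): ", paste(miss, collapse = ", "))
  invisible(panel)
}

#' Comprehensive instrument selection for one lipid
#'
#' Selects, from a multi-lipid variant panel, every variant whose
#' association with the target lipid reaches genome-wide significance.
#' This is the "use everything associated with the target lipid"
#' instrument; it maximizes power but may include variants acting
#' through other lipid fractions.
#'
#' @param panel Data frame with one row per variant and lipid-suffixed
#'   statistic columns (\code{beta_ldl}, \code{se_ldl}, \code{p_ldl},
#'   \code{beta_hdl}, ..., \code{p_tg}).
#' @param lipid Target lipid: one of \code{"ldl"}, \code{"hdl"},
#'   \code{"tg"}.
#' @param p_gws Genome-wide significance threshold, default 5e-8.
#' @return Character vector of selected rsids, in panel order.
#' @export
select_comprehensive <- function(panel, lipid, p_gws = 5e-8) {
  lipid <- match.arg(lipid, .LIPIDS)
  .check_panel(panel)
  stopifnot(p_gws > 0, p_gws < 1)
  p <- panel[[.panel_cols(lipid)["p"]]]
  sel <- panel$rsid[!is.na(p) & p < p_gws]
  if (length(sel) == 0)
    stop("no variant reaches p < ", p_gws, " for ", lipid,
         ": empty instrument")
  sel
}

#' Restrictive (pleiotropy-filtered) instrument selection
#'
#' Takes the comprehensive selection for the target lipid and removes
#' every variant that is also associated, at a secondary threshold, with
#' either of the other two lipid fractions.  The restricted set trades
#' power for specificity to the target lipid.
#'
#' @inheritParams select_comprehensive
#' @param p_secondary Exclusion threshold for association with the other
#'   lipids, default 1e-3.
#' @return Character vector of selected rsids, in panel order.
#' @export
select_restrictive <- function(panel, lipid, p_gws = 5e-8,
                               p_secondary = 1e-3) {
  lipid <- match.arg(lipid, .LIPIDS)
  stopifnot(p_secondary > 0, p_secondary <= 1)
  comp <- select_comprehensive(panel, lipid, p_gws)
  others <- setdiff(.LIPIDS, lipid)
  rows <- match(comp, panel$rsid)
  cross <- rep(FALSE, length(comp))
  for (ol in others) {
    p <- panel[[.panel_cols(ol)["p"]]][rows]
    cross <- cross | (!is.na(p) & p < p_secondary)
  }
  sel <- comp[!cross]
  if (length(sel) == 0)
    stop("restrictive selection for ", lipid, " is empty")
  sel
}

#' Specify a cis gene-region instrument
#'
#' Bundles the candidate variants around a drug-target gene with the
#' exposure they proxy.  The window size is carried as metadata only:
#' candidate lists are supplied, not recomputed from coordinates.
#'
#' @param gene Gene symbol (e.g. \code{"CETP"}).
#' @param lipid Target lipid whose associations define the instrument.
#' @param candidates Data frame with columns \code{rsid} and
#'   \code{pvalue} (target-lipid association p-values).
#' @param window_kb Flanking window, metadata only. Default 100.
#' @return A \code{gene_region_spec} object.
#' @export
gene_region_spec <- function(gene, lipid, candidates, window_kb = 100) {
  lipid <- match.arg(lipid, .LIPIDS)
  stopifnot(is.data.frame(candidates),
            all(c("rsid", "pvalue") %in% names(candidates)))
  structure(list(gene = gene, lipid = lipid,
                 candidates = candidates, window_kb = window_kb),
            class = "gene_region_spec")
}

#' Greedy LD-pruned selection of cis gene-region instruments
#'
#' Ranks genome-wide-significant candidates by ascending target-lipid
#' p-value (ties broken by rsid for determinism) and accepts each in
#' turn if its squared correlation with every previously accepted
#' variant stays below \code{r2_max}.  The retained variants are
#' mutually in low LD but may still be moderately correlated, which the
#' correlated-instrument estimators model explicitly.
#'
#' @param region A [gene_region_spec()].
#' @param ld Signed LD correlation matrix covering all candidates (see
#'   [load_ld_matrix()]).
#' @param p_gws Genome-wide significance threshold, default 5e-8.
#' @param r2_max Squared-correlation ceiling, default 0.4.
#' @return Character vector of selected rsids in acceptance order.
#' @export
select_gene_region <- function(region, ld, p_gws = 5e-8, r2_max = 0.4) {
  stopifnot(inherits(region, "gene_region_spec"),
            r2_max > 0, r2_max <= 1)
  cand <- region$candidates
  missing_ld <- setdiff(cand$rsid, rownames(ld))
  if (length(missing_ld) > 0)
    stop("candidate variant(s) absent from LD matrix: ",
         paste(missing_ld, collapse = ", "))
  cand <- cand[!is.na(cand$pvalue) & cand$pvalue < p_gws, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no genome-wide-significant candidate for ", region$gene)
  cand <- cand[order(cand$pvalue, cand$rsid), , drop = FALSE]
  accepted <- character(0)
  for (rs in cand$rsid) {
    if (length(accepted) == 0 ||
        all(ld[rs, accepted]^2 < r2_max))
      accepted <- c(accepted, rs)
  }
  accepted
}

#' Load a signed LD correlation matrix
#'
#' Reads a plain-text square matrix whose first row and first column
#' hold rsids.  Values must lie in [-1, 1] with a unit diagonal; small
#' numeric asymmetries (below 1e-6) are removed by averaging, anything
#' larger is an error.
#'
#' @param path Path to the matrix file (whitespace/tab separated).
#' @return A symmetric numeric matrix with rsid dimnames.
#' @export
load_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  validate_ld_matrix(m)
}

#' Validate (and symmetrize) an LD matrix
#' @param m Square numeric matrix with rsid dimnames.
#' @return The validated, exactly symmetric matrix.
#' @export
validate_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || !is.numeric(m))
    stop("LD matrix must be a square numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("LD matrix must carry rsid dimnames")
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column rsids differ")
  if (any(abs(m) > 1 + 1e-12))
    stop("LD correlations must lie in [-1, 1]")
  if (any(abs(diag(m) - 1) > 1e-6))
    stop("LD matrix diagonal must be 1")
  asym <- max(abs(m - t(m)))
  if (asym >= 1e-6)
    stop("LD matrix asymmetry ", format(asym), " exceeds 1e-6")
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Write an LD matrix in the package's plain-text format
#' @param m LD matrix with rsid dimnames.
#' @param path Output path.
#' @export
write_ld_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
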