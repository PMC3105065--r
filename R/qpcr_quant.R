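# qPCR quantification: standard-curve absolute quantification, taxon/total
# copy ratios, and 2^-ddCt relative expression.

#' Absolute copy number from a qPCR threshold cycle
#'
#' Inverts the standard curve `Ct = intercept + slope * log10(copies)`:
#' `copies = 10^((Ct - intercept) / slope)`, then scales by the template
#' dilution factor and normalizes by the soil dry weight in the extraction.
#'
#' @param ct Threshold cycle(s) (> 0).
#' @param curve_slope Standard-curve slope, cycles per log10(copies); must
#'   be negative (-3.3219 corresponds to 100 percent efficiency).
#' @param curve_intercept Standard-curve intercept, cycles.
#' @param dilution_factor Fold dilution between extract and reaction
#'   template (>= 1 scales copies back up). Default 1.
#' @param gdw_in_extraction Grams dry soil in the nucleic-acid extraction
#'   (> 0). Default 1.
#' @return Object of class `copy_quant`: `copies_in_reaction`,
#'   `copies_per_gdw`, `log10_copies` (of copies_per_gdw).
#' @examples
#' copies_from_ct(27, -3.3219, 37) # ~1024 copies
#' @export
copies_from_ct <- function(ct, curve_slope, curve_intercept,
                           dilution_factor = 1, gdw_in_extraction = 1) {
  if (any(curve_slope >= 0)) stop("invalid standard curve: slope must be < 0")
  if (any(ct <= 0)) stop("ct must be > 0")
  if (any(dilution_factor <= 0)) stop("dilution_factor must be > 0")
  if (any(gdw_in_extraction <= 0)) stop("gdw_in_extraction must be > 0")
  copies <- 10^((ct - curve_intercept) / curve_slope)
  per_gdw <- copies * dilution_factor / gdw_in_extraction
  structure(list(copies_in_reaction = copies, copies_per_gdw = per_gdw,
                 log10_copies = log10(per_gdw)),
            class = "copy_quant")
}

#' @export
print.copy_quant <- function(x, ...) {
  cat(sprintf("<copy_quant> %.4g copies gdw-1 (log10 = %.3f)\n",
              x$copies_per_gdw[1], x$log10_copies[1]))
  invisible(x)
}

#' Taxon-to-total copy ratio
#'
#' Ratio of a taxon-specific to a total (community) copy quantification.
#' Ratios above 1 are possible because assays differ in target copies per
#' cell; such values are flagged with a warning rather than rejected.
#'
#' @param taxon,total Copy numbers (numeric, copies gdw-1) or `copy_quant`
#'   objects.
#' @return Numeric ratio.
#' @export
copy_ratio <- function(taxon, total) {
  if (inherits(taxon, "copy_quant")) taxon <- taxon$copies_per_gdw
  if (inherits(total, "copy_quant")) total <- total$copies_per_gdw
  if (any(total <= 0)) stop("total copies must be > 0")
  r <- taxon / total
  if (any(r > 1)) {
    warning("copy ratio exceeds 1; assays may differ in per-cell target copies")
  }
  r
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold change in relative expression (transcript vs gene)
#' between two matched treatments. Each replicate contributes
#' `dCt = Ct(transcript) - Ct(gene)`; replicate pairs between the two
#' treatments give `ddCt_i = dCt_second_i - dCt_first_i` and per-pair fold
#' changes `2^-ddCt_i`. The reported fold change is the arithmetic mean of
#' the per-pair values with its standard error across pairs (so SEs can
#' exceed the mean for noisy assays); values above 1 indicate upregulation
#' in the second treatment. A geometric summary (`2^-mean(ddCt)`) is
#' returned alongside; it is exactly antisymmetric under swapping the two
#' treatments.
#'
#' @param delta_ct_first dCt replicates of the first treatment of the pair.
#' @param delta_ct_second dCt replicates of the second treatment.
#' @param pairing `"paired"` (default; replicates paired by index, requires
#'   equal lengths) or `"pooled"` (group means, SE by error propagation).
#' @return Object of class `relative_expression`: `fold_change`,
#'   `standard_error`, `fold_change_geometric`, `ddct`, `n_pairs`.
#' @examples
#' delta_delta_ct(1, 3) # single pair, fold change 0.25
#' @export
delta_delta_ct <- function(delta_ct_first, delta_ct_second,
                           pairing = c("paired", "pooled")) {
  pairing <- match.arg(pairing)
  a <- as.numeric(delta_ct_first)
  b <- as.numeric(delta_ct_second)
  if (length(a) == 0 || length(b) == 0) stop("empty replicate group")
  if (pairing == "paired") {
    if (length(a) != length(b)) {
      stop("paired mode requires equal replicate counts in both treatments")
    }
    ddct <- b - a
    folds <- 2^(-ddct)
    fc <- mean(folds)
    se <- if (length(folds) > 1) sd(folds) / sqrt(length(folds)) else NA_real_
    n <- length(folds)
  } else {
    ddct <- mean(b) - mean(a)
    se_dd <- sqrt(var(a) / length(a) + var(b) / length(b))
    fc <- 2^(-ddct)
    se <- log(2) * fc * se_dd   # first-order propagation
    n <- min(length(a), length(b))
    folds <- fc
  }
  structure(
    list(fold_change = fc, standard_error = se,
         fold_change_geometric = 2^(-mean(ddct)), ddct = ddct, n_pairs = n,
         pairing = pairing),
    class = "relative_expression"
  )
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("<relative_expression> 2^-ddCt = %.3g +/- %.3g (n = %d, %s)\n",
              x$fold_change, x$standard_error, x$n_pairs, x$pairing))
  invisible(x)
}

#' Relative-expression table from a qPCR plate
#'
#' Convenience wrapper building Table-style relative expression for a set
#' of matched treatment pairs from a long plate table. For each sample the
#' dCt is `Ct(transcript assay, cDNA) - Ct(gene assay, DNA)`, replicates
#' paired by their `replicate` index.
#'
#' @param plate Data frame with columns `assay`, `treatment`, `template`
#'   (`"DNA"`/`"cDNA"`), `replicate`, `ct`.
#' @param gene_assay,transcript_assay Assay names for the gene (DNA) and
#'   transcript (cDNA) quantifications.
#' @param pairs List of 2-element character vectors `c(first, second)` of
#'   treatment codes to compare.
#' @return Data frame with one row per pair: `pair`, `fold_change`,
#'   `standard_error`, `n_pairs`.
#' @export
expression_table <- function(plate, gene_assay, transcript_assay, pairs) {
  dct_of <- function(tr) {
    g <- plate[plate$assay == gene_assay & plate$treatment == tr &
                 plate$template == "DNA", , drop = FALSE]
    t <- plate[plate$assay == transcript_assay & plate$treatment == tr &
                 plate$template == "cDNA", , drop = FALSE]
    if (nrow(g) == 0 || nrow(t) == 0) {
      stop("missing gene or transcript records for treatment ", tr)
    }
    g <- g[order(g$replicate), ]; t <- t[order(t$replicate), ]
    if (!identical(g$replicate, t$replicate)) {
      stop("replicate indices of gene and transcript assays do not match for ", tr)
    }
    t$ct - g$ct
  }
  out <- lapply(pairs, function(p) {
    re <- delta_delta_ct(dct_of(p[1]), dct_of(p[2]))
    data.frame(pair = paste(p, collapse = "-"), fold_change = re$fold_change,
               standard_error = re$standard_error, n_pairs = re$n_pairs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
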