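# Bundled fixture: the eleven eQTLWAS association signals.

#' The bundled eQTLWAS association signals
#'
#' Eleven association signals between lead cis-eQTLs and cardiovascular
#' traits across eight unique genetic loci, as printed in the source table:
#' tag SNP, candidate gene(s), trait, per-trait sample size, effect size
#' per effect-allele copy, its standard error, and the p-value. The printed
#' p-value for the IL-6/rs600038 row lacks a minus sign in its exponent
#' ("4.12 x 10^22"), an evident typo; the table keeps the verbatim value in
#' \code{p_printed} and the sign-corrected value in \code{p}. Counting
#' signals against this fixture therefore uses distinct-SNP counting, never
#' re-thresholding of \code{p_printed}.
#'
#' @return data frame with columns \code{variant_id}, \code{genes}
#'   (semicolon-separated candidates), \code{trait}, \code{n}, \code{beta},
#'   \code{se}, \code{p_printed}, \code{p}.
#' @examples
#' tab <- eqtlwas_signals()
#' nrow(tab)                         # 11 association signals
#' length(unique(tab$variant_id))    # 8 unique tag SNPs
#' @export
eqtlwas_signals <- function() {
  path <- system.file("extdata", "table1_eqtlwas.tsv", package = "tissuemr",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(p_printed = "character"))
}
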