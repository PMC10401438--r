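#' The packaged HOX family gene list
#'
#' Returns the 39 canonical human HOX transcription-factor genes across the
#' four chromosomal clusters (11 HOXA, 10 HOXB, 9 HOXC, 9 HOXD). This is the
#' default feature set for consensus subtyping.
#'
#' @param with_cluster if `TRUE`, return a data frame with columns `gene` and
#'   `cluster`; otherwise a character vector of gene symbols.
#' @return character vector of 39 gene symbols, or a data frame.
#' @examples
#' length(hox_gene_list())  # 39
#' table(hox_gene_list(with_cluster = TRUE)$cluster)
#' @export
hox_gene_list <- function(with_cluster = FALSE) {
  path <- system.file("extdata", "hox_genes.tsv", package = "hoxsig",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (with_cluster) tab else tab$gene
}

#' The published five-gene HOX risk classifier
#'
#' A fixed reference signature over HOXA6, HOXC4, HOXC5, HOXC6 and HOXA-AS3
#' with low-risk centroid (0.61, 4.55, 0.74, 1.62, 0.43) and high-risk
#' centroid (5.70, 8.02, 4.93, 5.52, 4.46), on the log2 expression scale.
#' The centroids are the per-group mean expression of the five genes in the
#' good- and poor-prognosis training groups of the original derivation.
#'
#' Note: the stated centroid tuples are taken as authoritative; some printed
#' renderings of the expanded high-risk distance formula transpose the last
#' three components, and those variants are deliberately not reproduced here.
#'
#' @return a [centroid_signature] object.
#' @examples
#' sig <- published_classifier()
#' sig$genes
#' classify_samples(rbind(sig$high_centroid), sig)$risk  # "high"
#' @export
published_classifier <- function() {
  genes <- c("HOXA6", "HOXC4", "HOXC5", "HOXC6", "HOXA-AS3")
  new_centroid_signature(
    genes = genes,
    low_centroid  = c(0.61, 4.55, 0.74, 1.62, 0.43),
    high_centroid = c(5.70, 8.02, 4.93, 5.52, 4.46)
  )
}
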