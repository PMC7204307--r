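read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Shipped worked-example fixtures for signature distillation
#'
#' `top19_leading_edge_synthetic()` returns a synthetic reconstruction of
#' a top-19 CIN70 leading edge (rank-ordered): the seven mitotic PC-CIN
#' genes plus twelve CIN70 replication/repair/chromatin genes as
#' non-mitotic context. `mitosis_regulators_synthetic()` returns a
#' constructed mitosis-regulator annotation mask. Both are stand-ins
#' assembled for the worked example (their files carry a `_synthetic`
#' label), not published data.
#'
#' @return Character vector of gene symbols.
#' @examples
#' distill_signature(top19_leading_edge_synthetic(),
#'                   mitosis_regulators_synthetic(), k_max = 19)$genes
#' @export
top19_leading_edge_synthetic <- function() {
  read_gene_list(system.file("extdata",
                             "leading_edge_top19_synthetic.txt",
                             package = "cinscore", mustWork = TRUE))
}

#' @rdname top19_leading_edge_synthetic
#' @export
mitosis_regulators_synthetic <- function() {
  read_gene_list(system.file("extdata",
                             "mitosis_annotation_synthetic.txt",
                             package = "cinscore", mustWork = TRUE))
}
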