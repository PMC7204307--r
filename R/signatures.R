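# Shipped gene signatures.
#
# CIN70: the published 70-gene chromosomal-instability expression
# signature (genes whose expression tracks total chromosomal imbalance
# across tumors). The membership here is a reconstruction of that list
# with HGNC symbols modernized (CDK1 for CDC2, PBK for TOPK, AURKA for
# STK6, CDC45 for CDC45L, NCAPD2 for CNAP1, SRSF2 for SFRS2, ...);
# see the fixture file in inst/extdata and the package vignette.
#
# PC-CIN: the seven-gene prostate-specific mitotic distillation of the
# CIN70 leading edge: PBK, CEP55, UBE2C, MELK, TPX2, PTTG1, CDCA3.

.pccin_genes <- c("PBK", "CEP55", "UBE2C", "MELK", "TPX2", "PTTG1",
                  "CDCA3")

.cin70_genes <- c(
  "TPX2", "PRC1", "FOXM1", "CDK1", "TGIF2", "MCM2", "H2AFZ", "TOP2A",
  "PCNA", "UBE2C", "MELK", "TRIP13", "NCAPD2", "MCM7", "RNASEH2A",
  "RAD51AP1", "KIF20A", "CDC45", "MAD2L1", "ESPL1", "CCNB2", "FEN1",
  "TTK", "CCT5", "RFC4", "ATAD2", "CKAP5", "NUP205", "CDC20", "CKS2",
  "RRM2", "ELAVL1", "CCNB1", "RRM1", "AURKB", "MSH6", "EZH2", "CTPS1",
  "DKC1", "OIP5", "CDCA8", "PTTG1", "CEP55", "H2AFX", "NCAPH", "MCM10",
  "LSM4", "NCAPG2", "ASF1B", "ZWINT", "PBK", "ZWILCH", "CDCA3", "ECT2",
  "CDC6", "UNG", "MTCH2", "RAD21", "ACTL6A", "GPI", "SRSF2", "HDGF",
  "NXT1", "NEK2", "DHCR7", "AURKA", "NDUFAB1", "KIF4A", "SMC4", "CMAS"
)

#' Shipped CIN signatures
#'
#' `cin70_signature()` returns the 70-gene chromosomal-instability
#' signature (reconstructed membership with modernized gene symbols;
#' exact published membership is documented in the vignette).
#' `pccin_signature()` returns the seven-gene prostate-cancer CIN
#' signature (PBK, CEP55, UBE2C, MELK, TPX2, PTTG1, CDCA3), the mitotic
#' distillation of the CIN70 leading edge.
#'
#' @return A [gene_signature()].
#' @examples
#' length(cin70_signature()$genes)
#' pccin_signature()$genes
#' @export
cin70_signature <- function() gene_signature("CIN70", .cin70_genes)

#' @rdname cin70_signature
#' @export
pccin_signature <- function() gene_signature("PC-CIN", .pccin_genes)
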