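# Bundled gene lists from the TGF-beta cross-cell-type study this package's
# workflow follows, used as worked-example inputs for the reproducibility
# statistics.

#' Genes with differential whole-course expression in both human cell types
#'
#' The 18 genes reported with a differential TGF-beta response time course in
#' both human cell types (hepatocytes and mesenchymal stromal cells) of the
#' emulated study design.
#'
#' @format Character vector of 18 HGNC symbols.
#' @export
human_common_de_genes <- c(
  "ROR1", "C10orf10", "SMAD7", "FSTL3", "GADD45B", "JUNB", "ZFP36", "OLFM2",
  "SPTLC3", "ID1", "LMCD1", "SLC38A3", "GXYLT2", "SKIL", "HES1", "RASGEF1B",
  "CITED2", "PDGFA"
)

#' Human-common genes reproduced in the independent validation time course
#'
#' The 11 of the [human_common_de_genes] that also showed a differential
#' TGF-beta response time course in the independent A549 lung adenocarcinoma
#' dataset (GSE17708; documented for provenance, never fetched).
#'
#' @format Character vector of 11 HGNC symbols.
#' @export
a549_reproduced_de_genes <- c(
  "ROR1", "SMAD7", "FSTL3", "GADD45B", "JUNB", "ZFP36", "ID1", "LMCD1",
  "GXYLT2", "SKIL", "HES1"
)
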