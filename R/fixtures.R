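#' Packaged synthetic fixtures
#'
#' The package ships three small synthetic fixtures under `extdata`:
#' a perinatal reference chart (weeks 34--42 by sex and parity, grams) and two
#' variant annotation tables mirroring the published marginal structure of
#' genome-wide significant blood-pressure loci -- a 41-SNP panel associated
#' with SBP/DBP/MAP/PP (18 vasculature-related / 12 unlikely related / 11
#' unknown, 7 of them DBP-discordant) and a 67-SNP SBP panel at p < 1e-6
#' (21 / 30 / 16). The variant identities, alleles and positions are
#' synthetic stand-ins; only the classification structure is meaningful.
#'
#' @return `placmed_chart()`: a `reference_chart`; the annotation accessors:
#'   annotation data.frames (see [read_annotation()]).
#' @export
placmed_chart <- function() {
  read_reference_chart(
    system.file("extdata", "reference_chart_synthetic.tsv",
                package = "placmed", mustWork = TRUE))
}

#' @rdname placmed_chart
#' @export
annotation_bp41 <- function() {
  read_annotation(
    system.file("extdata", "annotation_bp41_synthetic.tsv",
                package = "placmed", mustWork = TRUE))
}

#' @rdname placmed_chart
#' @export
annotation_sbp67 <- function() {
  read_annotation(
    system.file("extdata", "annotation_sbp67_synthetic.tsv",
                package = "placmed", mustWork = TRUE))
}
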