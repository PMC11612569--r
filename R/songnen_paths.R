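#' Songnen Plain standardized path coefficients, 2000-2020
#'
#' The per-year standardized structural edge coefficients of the habitat
#' quality driver analysis for the Songnen Plain (years 2000, 2010, 2018,
#' 2020). Edges marked `published` in the `source` column carry the
#' coefficients as reported for that case study; edges marked
#' `reconstructed_from_channel_product_*` were solved from the reported
#' per-channel indirect products (the product of coefficients along the
#' channel), so every reported channel product — and hence every total
#' effect — is preserved exactly. Where only a channel product was
#' reported, the split between the two edges of the channel is nominal:
#' it cancels in every path product and does not affect any decomposition.
#'
#' @param year one of 2000, 2010, 2018, 2020.
#' @return data.frame with columns `from`, `to`, `coef`, `source`,
#'   usable directly with [effect_decomposition()] and
#'   [total_effects_matrix()].
#' @examples
#' eff <- effect_decomposition(songnen_paths(2010), "Topography", "HQ")
#' round(eff$total, 2)  # 0.32
#' @export
songnen_paths <- function(year) {
  year <- as.integer(year)
  if (!year %in% c(2000L, 2010L, 2018L, 2020L))
    stop("available years: 2000, 2010, 2018, 2020")
  path <- system.file("extdata", sprintf("paths_%d.csv", year),
                      package = "habiquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
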