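# Packaged reference table of P1BS elements upstream of the 33 maize
# ZmPap genes (counts and signed locations within 2500 bp of the
# translational start, ASCII minus signs) together with the predicted
# subcellular localization of each protein (S secretory, M mitochondrial,
# C chloroplast, O other).

#' Read the packaged maize ZmPap P1BS reference table
#'
#' Loads the published per-gene P1BS survey for the 33-member maize PAP
#' family: element count, signed locations (bp upstream of the predicted
#' translational start, proximal first) and predicted subcellular
#' localization. The loader validates the table (33 rows, count equal to
#' the number of locations, locations within `[-2500, -1]`) and errors on
#' any mismatch.
#'
#' @return Tibble (class `pap_p1bs`) with columns `gene_id`, `p1bs_count`,
#'   `locations` (integer list-column), `location_str`, `localization`.
#' @export
#' @examples
#' ref <- read_p1bs_reference()
#' summarize_p1bs(ref)
read_p1bs_reference <- function() {
  path <- system.file("extdata", "zmpap_p1bs.tsv", package = "papfam")
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    p1bs_count = readr::col_integer(),
    p1bs_locations = readr::col_character(),
    localization = readr::col_character()
  ))
  out <- raw |>
    dplyr::mutate(
      locations = purrr::map(.data$p1bs_locations, function(s) {
        if (is.na(s) || s == "") integer(0)
        else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
      }),
      location_str = purrr::map_chr(.data$locations, paste, collapse = ", ")
    ) |>
    dplyr::select(gene_id = "gene", "p1bs_count", "locations",
                  "location_str", "localization")
  if (nrow(out) != 33) {
    stop("corrupt P1BS reference: expected 33 rows, got ", nrow(out))
  }
  if (!all(out$p1bs_count == purrr::map_int(out$locations, length))) {
    stop("corrupt P1BS reference: count/location mismatch")
  }
  locs <- unlist(out$locations)
  if (length(locs) > 0 && (any(locs < -2500) || any(locs > -1))) {
    stop("corrupt P1BS reference: locations outside [-2500, -1]")
  }
  if (!all(out$localization %in% c("S", "M", "C", "O"))) {
    stop("corrupt P1BS reference: unknown localization class")
  }
  class(out) <- c("pap_p1bs", class(out))
  out
}
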