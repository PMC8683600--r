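# Country-name normalisation to ISO-3166 alpha-3 codes.
# The lookup covers the countries and territories implicated in the
# Nigeria-linked pangolin trade plus common aliases; any string already in
# valid alpha-3 form passes through unchanged. Hong Kong is kept as a
# distinct territory node (HKG).

.country_aliases <- c(
  "nigeria"                          = "NGA",
  "cameroon"                         = "CMR",
  "china"                            = "CHN",
  "people's republic of china"       = "CHN",
  "hong kong"                        = "HKG",
  "hong kong sar"                    = "HKG",
  "vietnam"                          = "VNM",
  "viet nam"                         = "VNM",
  "laos"                             = "LAO",
  "lao people's democratic republic" = "LAO",
  "lao pdr"                          = "LAO",
  "cambodia"                         = "KHM",
  "thailand"                         = "THA",
  "singapore"                        = "SGP",
  "malaysia"                         = "MYS",
  "indonesia"                        = "IDN",
  "india"                            = "IND",
  "kenya"                            = "KEN",
  "ghana"                            = "GHA",
  "turkey"                           = "TUR",
  "turkiye"                          = "TUR",
  "france"                           = "FRA",
  "netherlands"                      = "NLD",
  "the netherlands"                  = "NLD",
  "gabon"                            = "GAB",
  "niger"                            = "NER",
  "benin"                            = "BEN",
  "togo"                             = "TGO",
  "democratic republic of the congo" = "COD",
  "democratic republic of congo"     = "COD",
  "dr congo"                         = "COD",
  "drc"                              = "COD",
  "republic of congo"                = "COG",
  "republic of the congo"            = "COG",
  "congo"                            = "COG",
  "congo-brazzaville"                = "COG",
  "central african republic"         = "CAF",
  "car"                              = "CAF",
  "cote d'ivoire"                    = "CIV",
  "côte d'ivoire"               = "CIV",
  "ivory coast"                      = "CIV",
  "liberia"                          = "LBR",
  "sierra leone"                     = "SLE",
  "guinea"                           = "GIN",
  "south africa"                     = "ZAF",
  "zimbabwe"                         = "ZWE",
  "uganda"                           = "UGA",
  "united kingdom"                   = "GBR",
  "uk"                               = "GBR",
  "united states"                    = "USA",
  "usa"                              = "USA",
  "germany"                          = "DEU",
  "belgium"                          = "BEL",
  "japan"                            = "JPN",
  "south korea"                      = "KOR",
  "republic of korea"                = "KOR",
  "taiwan"                           = "TWN",
  "philippines"                      = "PHL",
  "myanmar"                          = "MMR",
  "burma"                            = "MMR"
)

#' Normalise country names to ISO-3166 alpha-3 codes
#'
#' Maps country and territory names (including historical and colloquial
#' aliases such as "Ivory Coast" or "DR Congo") to alpha-3 codes. Strings
#' already consisting of three ASCII letters are upper-cased and passed
#' through, so curated files may mix codes and names freely.
#'
#' @param x character vector of country names or codes.
#' @param strict if `TRUE`, unknown names raise an error; otherwise they
#'   return `NA` with a warning.
#' @return character vector of alpha-3 codes.
#' @examples
#' normalize_country(c("Nigeria", "Viet Nam", "HKG", "Ivory Coast"))
#' @export
normalize_country <- function(x, strict = FALSE) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  is_code <- grepl("^[A-Za-z]{3}$", x) & !(tolower(x) %in% names(.country_aliases))
  out[is_code] <- toupper(x[is_code])
  rest <- !is_code & !is.na(x) & nzchar(x)
  out[rest] <- unname(.country_aliases[tolower(x[rest])])
  bad <- rest & is.na(out)
  if (any(bad)) {
    msg <- paste0("unrecognised country name(s): ",
                  paste(unique(x[bad]), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out
}

#' Split a route string into a normalised country vector
#'
#' Routes are stored in CSV as ordered country lists separated by `|`, `;`
#' or `->`. Each element is normalised with [normalize_country()].
#'
#' @param x character vector of route strings.
#' @return list of character vectors of alpha-3 codes, in travel order.
#' @examples
#' parse_route("Cote d'Ivoire | Nigeria | Vietnam")
#' @export
parse_route <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    parts <- strsplit(s, "\\||;|->", perl = TRUE)[[1]]
    parts <- trimws(parts)
    normalize_country(parts[nzchar(parts)])
  })
}
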