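#' @keywords internal
"_PACKAGE"

## Shared helpers: variant keys, gestational-age parsing, input checks.

#' Canonical string identifier for a variant
#'
#' Variants are keyed by chromosome, 1-based position, reference allele and
#' alternate allele on GRCh37/hg19 (`"chr"`-prefixed chromosome names).
#' Two observations with the same key are the same variant for allele
#' counting and reference-frequency lookup.
#'
#' @param chrom Chromosome name(s), e.g. `"chr12"`.
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings (A/C/G/T, possibly multi-base for indels).
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(alt))
  if (any(pos < 1)) stop("variant position must be >= 1")
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) stop("ref/alt alleles must be non-empty A/C/G/T strings")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Parse a genomic-change string into key components
#'
#' Accepts substitution notation of the form `"chr12:22063090C>T"`.
#' Deletion/insertion range notation carries no allele sequence and cannot be
#' normalized without the reference genome; such strings are rejected.
#'
#' @param x Character vector of genomic-change strings.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
parse_genomic_change <- function(x) {
  m <- regmatches(x, regexec("^(chr[0-9XYM]+):([0-9]+)([ACGT]+)>([ACGT]+)$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed genomic-change string (expected e.g. 'chr12:22063090C>T'): ",
         paste(x[bad], collapse = ", "))
  }
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    ref = vapply(m, `[`, "", 4L),
    alt = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

#' Gestational age in decimal weeks
#'
#' Parses the `"weeks+days"` notation used in clinical records (`"32+3"` is
#' 32 weeks 3 days). A bare number is taken as completed weeks; the token
#' `"full_term"` is mapped to 40 weeks by convention; `"-"` or `NA` is
#' unknown.
#'
#' @param ga Character vector of gestational-age tokens.
#' @return Numeric vector of weeks (`NA` where unknown).
#' @export
ga_weeks <- function(ga) {
  out <- rep(NA_real_, length(ga))
  ga <- as.character(ga)
  known <- !is.na(ga) & ga != "-" & ga != ""
  ft <- known & ga == "full_term"
  out[ft] <- 40
  wd <- known & grepl("^[0-9]+\\+[0-9]+$", ga)
  if (any(wd)) {
    parts <- strsplit(ga[wd], "+", fixed = TRUE)
    out[wd] <- vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 7, 0)
  }
  wk <- known & grepl("^[0-9]+$", ga)
  out[wk] <- as.numeric(ga[wk])
  bad <- known & !ft & !wd & !wk
  if (any(bad)) stop("unparseable gestational age: ", paste(ga[bad], collapse = ", "))
  out
}

## internal: "-"/"" -> NA for numeric columns read as character
.na_dash_num <- function(x) {
  x <- as.character(x)
  x[x %in% c("-", "")] <- NA_character_
  suppressWarnings(out <- as.numeric(x))
  if (any(is.na(out) & !is.na(x))) stop("non-numeric value: ",
                                        paste(x[is.na(out) & !is.na(x)], collapse = ", "))
  out
}

.assert_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
    stop(name, " must be a single non-negative integer")
  as.integer(x)
}
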