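## Gene panel model: the 70-gene cardiac channelopathy/cardiomyopathy panel,
## disease-association codes 1-15, and category lookup for burden grouping.

PANEL_CATEGORIES <- c("channelopathy", "cardiomyopathy")

#' Load a gene-panel definition
#'
#' A panel file is tab-separated text with header
#' `symbol<TAB>category<TAB>disease_codes`; `category` is one of
#' `channelopathy` or `cardiomyopathy` and `disease_codes` is a
#' comma-separated list of integer association codes in 1..15
#' (1 = LQTS, 2 = BrS, 3 = CPVT, ..., 12 = DCM, 14 = HCM; see the packaged
#' default panel). Gene symbols are uppercased on read and must be unique.
#'
#' Genes whose association codes span both disease families (e.g. PKP2 is
#' both ARVC- and BrS-associated) take the single category assigned in the
#' file; `category_override` reassigns individual symbols without editing
#' the file.
#'
#' @param source Path to a panel definition file; defaults to the packaged
#'   70-gene cardiac panel (23 channelopathy + 47 cardiomyopathy genes).
#' @param category_override Named character vector mapping gene symbols to a
#'   replacement category, e.g. `c(PKP2 = "channelopathy")`.
#' @return A `gene_panel`: data.frame with columns `symbol`, `category`,
#'   `disease_codes` (comma-separated string).
#' @export
load_panel <- function(source = default_panel_file(), category_override = NULL) {
  if (!file.exists(source)) stop("panel file not found: ", source)
  df <- utils::read.delim(source, colClasses = "character")
  need <- c("symbol", "category", "disease_codes")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$symbol <- toupper(trimws(df$symbol))
  if (nrow(df) > 0) {
    bad <- which(df$symbol == "" | !df$category %in% PANEL_CATEGORIES)
    if (length(bad))
      stop("malformed panel row at line ", bad[1] + 1L,
           " (empty symbol or unknown category '", df$category[bad[1]], "')")
    dup <- df$symbol[duplicated(df$symbol)]
    if (length(dup)) stop("duplicate gene symbol in panel: ",
                          paste(unique(dup), collapse = ", "))
    codes <- strsplit(df$disease_codes, ",", fixed = TRUE)
    ok <- vapply(codes, function(cs) {
      cs <- suppressWarnings(as.integer(trimws(cs)))
      length(cs) > 0 && !anyNA(cs) && all(cs >= 1 & cs <= 15)
    }, TRUE)
    if (!all(ok))
      stop("malformed disease codes at line ", which(!ok)[1] + 1L,
           " (need comma-separated integers in 1..15)")
  }
  if (!is.null(category_override)) {
    ov <- toupper(names(category_override))
    if (!all(category_override %in% PANEL_CATEGORIES))
      stop("override categories must be one of: ",
           paste(PANEL_CATEGORIES, collapse = ", "))
    missing <- setdiff(ov, df$symbol)
    if (length(missing)) stop("override for non-panel gene: ",
                              paste(missing, collapse = ", "))
    df$category[match(ov, df$symbol)] <- unname(category_override)
  }
  structure(df, class = c("gene_panel", "data.frame"))
}

#' Path to the packaged default 70-gene panel file
#' @export
default_panel_file <- function() {
  system.file("extdata", "cardiac_panel_70.tsv", package = "cardioburden",
              mustWork = TRUE)
}

#' Write a panel definition back to file
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` reproduces `p`.
#'
#' @param panel A `gene_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Disease category of a panel gene
#'
#' @param panel A `gene_panel`.
#' @param symbol Gene symbol(s); matching is case-insensitive.
#' @return Character vector of categories (`"channelopathy"` or
#'   `"cardiomyopathy"`). Symbols absent from the panel are an error.
#' @export
category_of <- function(panel, symbol) {
  stopifnot(inherits(panel, "gene_panel"))
  idx <- match(toupper(symbol), panel$symbol)
  if (anyNA(idx))
    stop("gene symbol(s) not on panel: ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  panel$category[idx]
}

#' @export
print.gene_panel <- function(x, ...) {
  tab <- table(factor(x$category, levels = PANEL_CATEGORIES))
  cat("Gene panel:", nrow(x), "genes (",
      tab[["channelopathy"]], "channelopathy,",
      tab[["cardiomyopathy"]], "cardiomyopathy )\n")
  invisible(x)
}
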