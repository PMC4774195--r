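#' Ordinal scale for the X-Gal colorimetric test
#'
#' The X-Gal reporter is scored on a 7-level ordinal scale running from a
#' clear negative to a strong positive.  Marks are encoded as contiguous
#' integer codes starting at 0, strictly increasing with the ordering.
#'
#' @param marks Character vector of mark labels, ordered from weakest to
#'   strongest.  Defaults to the standard scale
#'   `'-' < '-?' < '?' < '+?' < '+' < '++' < '+++'`.
#' @return An object of class `ordinal_scale`: a list with elements `marks`
#'   and `codes` (integers `0:(length(marks) - 1)`).
#' @examples
#' sc <- ordinal_scale()
#' mark_to_code("+?", sc)
#' @export
ordinal_scale <- function(marks = c("-", "-?", "?", "+?", "+", "++", "+++")) {
  marks <- as.character(marks)
  if (anyDuplicated(marks)) abort("ordinal scale marks must be unique")
  structure(list(marks = marks, codes = seq_along(marks) - 1L),
            class = "ordinal_scale")
}

#' Convert X-Gal marks to integer codes and back
#'
#' @param x Character vector of marks (`mark_to_code`) or integer codes
#'   (`code_to_mark`).
#' @param scale An [ordinal_scale()].
#' @return Integer codes, or character marks.
#' @export
mark_to_code <- function(x, scale = ordinal_scale()) {
  idx <- match(as.character(x), scale$marks)
  if (anyNA(idx) && !anyNA(x)) {
    bad <- unique(x[is.na(idx)])
    abort(paste0("unknown X-Gal mark(s): ", paste(bad, collapse = ", ")))
  }
  scale$codes[idx]
}

#' @rdname mark_to_code
#' @export
code_to_mark <- function(x, scale = ordinal_scale()) {
  scale$marks[match(as.integer(x), scale$codes)]
}

#' The transcriptional regulators screened in the auxin signalling network
#'
#' The two-way screen covered 49 of the 52 Arabidopsis auxin transcriptional
#' regulators (ARF15, 21 and 23 could not be cloned): 20 ARF and 29 Aux/IAA.
#' ARF5, 6, 7, 8 and 19 are the transcriptional activators (ARF+); the other
#' ARF act as repressors (ARF-); Aux/IAA lack a DNA-binding domain.
#'
#' @return A tibble with columns `protein` and `family`
#'   (`"ARF+"`, `"ARF-"` or `"AuxIAA"`), 49 rows.
#' @examples
#' aux_regulators()
#' @export
aux_regulators <- function() {
  arf <- paste0("ARF", c(1:14, 16:20, 22))
  iaa <- paste0("IAA", c(1:20, 26:34))
  tibble(protein = c(arf, iaa),
         family = protein_family(c(arf, iaa)))
}

arf_activators <- c("ARF5", "ARF6", "ARF7", "ARF8", "ARF19")

protein_family <- function(ids) {
  dplyr::case_when(
    ids %in% arf_activators ~ "ARF+",
    grepl("^ARF", ids) ~ "ARF-",
    grepl("^IAA", ids) ~ "AuxIAA",
    TRUE ~ NA_character_
  )
}

# Strip the Gal4 fusion prefix ("AD-" / "BD-"); orientation is already
# captured by the bait/prey columns.
normalize_protein_id <- function(ids) sub("^(AD|BD)-", "", trimws(ids))

parse_his3 <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  pct <- grepl("%\\s*$", x)
  num <- suppressWarnings(as.numeric(sub("%\\s*$", "", x)))
  out[!is.na(num)] <- num[!is.na(num)]
  out[pct & !is.na(num)] <- num[pct & !is.na(num)] / 100
  bad <- !is.na(x) & x != "" & x != "NA" & is.na(num)
  if (any(bad)) {
    abort(paste0("unparseable HIS3 value(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  if (any(out < 0, na.rm = TRUE)) abort("HIS3 ratios must be non-negative")
  out
}

#' Read a two-way Y2H interaction table
#'
#' Parses a delimited text table with one row per *ordered* bait-prey pair
#' and columns `bait`, `prey`, `xgal`, `his3`.  Protein ids may carry the
#' Gal4-fusion prefixes `AD-`/`BD-`, which are stripped.  HIS3 optical
#' density ratios may be given as plain ratios or percent-suffixed values
#' (`"119 %"` becomes 1.19); empty values become missing.  Lines starting
#' with `#` are skipped.
#'
#' @param path Path to a TSV or CSV file (the delimiter is auto-detected).
#' @param scale An [ordinal_scale()] against which X-Gal marks are checked.
#' @return A list of class `y2h_data` with elements
#'   \describe{
#'     \item{roster}{tibble `protein`, `family`: the union of ids in order
#'       of first appearance.}
#'     \item{records}{tibble `bait`, `prey`, `xgal` (integer code),
#'       `his3` (ratio, possibly `NA`).}
#'     \item{scale}{the ordinal scale used.}
#'   }
#' @export
parse_y2h_table <- function(path, scale = ordinal_scale()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) abort("empty Y2H table")
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  tab <- readr::read_delim(I(paste(lines, collapse = "\n")), delim = delim,
                           col_types = readr::cols(.default = "c"),
                           trim_ws = TRUE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("bait", "prey", "xgal", "his3")
  if (!all(need %in% names(tab))) {
    abort(paste0("Y2H table must have columns ", paste(need, collapse = ", ")))
  }
  records <- tibble(
    bait = normalize_protein_id(tab$bait),
    prey = normalize_protein_id(tab$prey),
    xgal = mark_to_code(tab$xgal, scale),
    his3 = parse_his3(tab$his3)
  )
  dup <- duplicated(records[c("bait", "prey")])
  if (any(dup)) {
    abort(paste0("duplicate ordered pair(s): ",
                 paste(unique(paste(records$bait[dup], records$prey[dup],
                                    sep = " / ")), collapse = "; ")))
  }
  ids <- unique(c(rbind(records$bait, records$prey)))
  new_y2h_data(tibble(protein = ids, family = protein_family(ids)),
               records, scale)
}

new_y2h_data <- function(roster, records, scale = ordinal_scale()) {
  structure(list(roster = roster, records = records, scale = scale),
            class = "y2h_data")
}

#' @export
print.y2h_data <- function(x, ...) {
  cat("Y2H interaction data: ", nrow(x$roster), " proteins, ",
      nrow(x$records), " ordered test records\n", sep = "")
  invisible(x)
}

#' Write a Y2H record table
#'
#' Canonical TSV writer for the `bait`, `prey`, `xgal`, `his3` schema; the
#' inverse of [parse_y2h_table()] (ratios round-trip at full double
#' precision).
#'
#' @param data A `y2h_data` object or a records tibble.
#' @param path Output file path.
#' @param scale Ordinal scale used to render mark labels.
#' @return `path`, invisibly.
#' @export
write_y2h_table <- function(data, path, scale = ordinal_scale()) {
  records <- if (inherits(data, "y2h_data")) data$records else data
  out <- tibble(bait = records$bait, prey = records$prey,
                xgal = code_to_mark(records$xgal, scale),
                his3 = records$his3)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict the roster to the analysed regulators
#'
#' The study removed ARF3 and ARF17 (no dimerisation domain III/IV) and
#' ARF11 (no connections in the published binary network), taking the
#' 49-protein screen down to the 46 proteins used for network modelling.
#'
#' @param data A `y2h_data` object.
#' @param exclusions Character vector of protein ids to drop.  Ids not in
#'   the roster produce a warning, not an error.
#' @return A `y2h_data` object restricted to the remaining proteins,
#'   roster order preserved.
#' @examples
#' \dontrun{
#' filter_regulators(dat, c("ARF3", "ARF17", "ARF11"))
#' }
#' @export
filter_regulators <- function(data, exclusions = c("ARF3", "ARF17", "ARF11")) {
  stopifnot(inherits(data, "y2h_data"))
  missing_ids <- setdiff(exclusions, data$roster$protein)
  if (length(missing_ids)) {
    warn(paste0("exclusion id(s) not in roster: ",
                paste(missing_ids, collapse = ", ")))
  }
  keep <- !data$roster$protein %in% exclusions
  roster <- data$roster[keep, , drop = FALSE]
  records <- dplyr::filter(data$records,
                           .data$bait %in% roster$protein,
                           .data$prey %in% roster$protein)
  new_y2h_data(roster, records, data$scale)
}

#' Cohort accounting for a two-way replicated screen
#'
#' For `n` regulators tested pairwise (self-pairs included), each unordered
#' pair tested in both orientations and each orientation replicated.
#'
#' @param n_regulators Number of proteins screened.
#' @param n_ways Orientations per unordered pair (default 2: each protein as
#'   bait and as prey).
#' @param n_replicates Independent biological tests per orientation
#'   (default 2).
#' @return A one-row tibble with `ordered_pairs` (\eqn{n^2}),
#'   `unordered_pairs` (\eqn{n(n+1)/2}) and
#'   `total_tests` (`unordered_pairs * n_ways * n_replicates`).
#' @examples
#' cohort_accounting(49)  # 2401 ordered, 1225 unordered, 4900 tests
#' @export
cohort_accounting <- function(n_regulators, n_ways = 2, n_replicates = 2) {
  stopifnot(n_regulators >= 1)
  n <- as.numeric(n_regulators)
  unordered <- n * (n + 1) / 2
  tibble(n_regulators = n,
         ordered_pairs = n^2,
         unordered_pairs = unordered,
         total_tests = unordered * n_ways * n_replicates)
}
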