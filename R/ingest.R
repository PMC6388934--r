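## Ingestion of the published supplementary lineage workbook (XLSX).
##
## The workbook layout is not standardized, so the ingester auto-detects,
## per sheet, one of two layouts and documents what it found:
##   * long:  three columns interpretable as (pedigree id, binary position
##            label, trait value), possibly with extra columns;
##   * wide:  one row per pedigree, one column per binary position label
##            (column headers are the labels), an optional id column first.
## Sheets are matched to datasets by name. Expected replicate counts
## (T cells n = 19, worm n = 10, branching simulation n = 20) are checked
## and a mismatch is an explicit error describing the detected layout.

dataset_patterns <- c(
  tcell = "t[ -_]?cell|lymph|cd8",
  worm = "worm|elegans|pha",
  branching = "branch|simul"
)

dataset_n <- c(tcell = 19L, worm = 10L, branching = 20L)

#' Ingest lineage pedigrees from the supplementary XLSX workbook
#'
#' Extracts one of the three published datasets (T-cell lifetime-averaged
#' cell area, worm PHA-4 reporter intensity, or the simulated branching
#' process) from the supplementary workbook into a pedigree table. Sheet
#' names are matched case-insensitively against the dataset; the sheet
#' layout (long or wide, see the package vignette) is auto-detected and the
#' detected layout is reported. The number of pedigrees found is validated
#' against the published counts (19 / 10 / 20).
#'
#' @param path path to the XLSX workbook.
#' @param dataset one of `"tcell"`, `"worm"`, `"branching"`.
#' @param G analysis depth passed to [as_pedigree_table()] (default: the
#'   deepest generation present; the T-cell analyses use `G = 5`).
#' @param sheet optional explicit sheet name or index, bypassing name
#'   matching.
#' @return a pedigree table tibble.
#' @export
ingest_lineage_xlsx <- function(path, dataset = c("tcell", "worm", "branching"),
                                G = NULL, sheet = NULL) {
  dataset <- match.arg(dataset)
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("the `readxl` package is required for XLSX ingestion", call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sheets <- readxl::excel_sheets(path)
  if (is.null(sheet)) {
    hit <- grepl(dataset_patterns[[dataset]], sheets, ignore.case = TRUE)
    if (!any(hit)) {
      stop(sprintf(
        "no sheet matching dataset '%s' (pattern '%s'); sheets present: %s",
        dataset, dataset_patterns[[dataset]], paste(sheets, collapse = ", ")),
        call. = FALSE)
    }
    sheet <- sheets[which(hit)[1]]
  }
  raw <- readxl::read_excel(path, sheet = sheet, col_types = "text",
                            .name_repair = "minimal")
  tbl <- parse_lineage_sheet(raw, sheet)
  n_found <- dplyr::n_distinct(tbl$pedigree)
  n_want <- dataset_n[[dataset]]
  if (n_found != n_want) {
    stop(sprintf(
      "sheet '%s' parsed as %s layout with %d pedigree(s); expected %d for dataset '%s'",
      sheet, attr(tbl, "layout"), n_found, n_want, dataset), call. = FALSE)
  }
  message(sprintf("sheet '%s': %s layout, %d pedigrees", sheet,
                  attr(tbl, "layout"), n_found))
  if (dataset == "tcell" && is.null(G)) G <- 5L
  as_pedigree_table(tbl, G = G)
}

# Detect long vs wide layout of a raw character sheet and return a
# (pedigree, position, value) tibble with attr "layout".
parse_lineage_sheet <- function(raw, sheet_name = "?") {
  nm <- names(raw)
  label_cols <- which(is_position(nm))
  if (length(label_cols) >= 3) {
    # wide: position labels in the header
    id_cols <- setdiff(seq_along(nm), label_cols)
    ids <- if (length(id_cols) >= 1) as.character(raw[[id_cols[1]]])
           else as.character(seq_len(nrow(raw)))
    long <- tibble::tibble(pedigree = rep(ids, length(label_cols)),
                           position = rep(nm[label_cols], each = nrow(raw)),
                           value = suppressWarnings(
                             as.numeric(unlist(raw[label_cols]))))
    return(structure(long, layout = "wide"))
  }
  # long: find a column of valid labels, a value column, an id column
  frac_label <- vapply(raw, function(col) mean(is_position(col), na.rm = TRUE),
                       numeric(1))
  pos_col <- which(frac_label > 0.9)[1]
  if (is.na(pos_col)) {
    stop(sprintf(
      paste0("cannot detect layout of sheet '%s': expected either position ",
             "labels (^1[01]*$) as column headers (wide layout) or a column ",
             "of position labels (long layout); header was: %s"),
      sheet_name, paste(utils::head(nm, 10), collapse = ", ")), call. = FALSE)
  }
  rest <- setdiff(seq_along(raw), pos_col)
  # the trait column is the mostly-numeric column with the most distinct
  # values; the id column has few distinct values (one per pedigree)
  score <- vapply(raw[rest], function(col) {
    v <- suppressWarnings(as.numeric(col))
    mean(!is.na(v)) * dplyr::n_distinct(v, na.rm = TRUE)
  }, numeric(1))
  val_col <- rest[which.max(score)]
  id_col <- setdiff(rest, val_col)[1]
  if (is.na(id_col)) stop(sprintf(
    "long layout in sheet '%s' needs a pedigree id column", sheet_name),
    call. = FALSE)
  long <- tibble::tibble(
    pedigree = as.character(raw[[id_col]]),
    position = as.character(raw[[pos_col]]),
    value = suppressWarnings(as.numeric(raw[[val_col]]))
  )
  structure(long, layout = "long")
}
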