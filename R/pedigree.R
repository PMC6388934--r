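## Pedigree tables: the canonical long-format container. One row per
## (pedigree, position) with a numeric trait value; NA marks a missing cell.

#' Construct and validate a pedigree table
#'
#' A pedigree table is a tibble with columns `pedigree` (replicate id),
#' `position` (binary lineal-position label) and `value` (numeric trait,
#' `NA` for missing cells). `as_pedigree_table()` validates labels, rejects
#' duplicated (pedigree, position) rows, and pads every pedigree to the
#' complete `G`-generation layout, marking unobserved positions missing.
#' Positions deeper than `G` are dropped (with a message).
#'
#' @param data a data frame with the three columns above (names configurable).
#' @param G analysis depth; defaults to the deepest generation present.
#' @param pedigree_col,position_col,value_col column names in `data`.
#' @param quiet suppress the ingestion summary message.
#' @return a tibble with columns `pedigree`, `position`, `value`, exactly
#'   `n_pedigrees * (2^G - 1)` rows, ordered by pedigree then canonical
#'   position order, with attribute `"G"`.
#' @examples
#' tbl <- simulate_branching(n = 3, G = 3, h = 0.8, seed = 1)
#' as_pedigree_table(tbl, G = 2)
#' @export
as_pedigree_table <- function(data, G = NULL,
                              pedigree_col = "pedigree",
                              position_col = "position",
                              value_col = "value",
                              quiet = FALSE) {
  need <- c(pedigree_col, position_col, value_col)
  if (!all(need %in% names(data))) {
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(data)), collapse = ", ")),
         call. = FALSE)
  }
  tbl <- tibble::tibble(
    pedigree = data[[pedigree_col]],
    position = as.character(data[[position_col]]),
    value = as.numeric(data[[value_col]])
  )
  bad <- !is_position(tbl$position)
  if (any(bad)) {
    stop(sprintf("invalid position label(s) at row(s) %s: %s",
                 paste(utils::head(which(bad), 5), collapse = ", "),
                 paste(utils::head(unique(tbl$position[bad]), 5), collapse = ", ")),
         call. = FALSE)
  }
  dup <- duplicated(tbl[c("pedigree", "position")])
  if (any(dup)) {
    stop(sprintf("duplicated (pedigree, position) row(s): %s",
                 paste(utils::head(which(dup), 5), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(G)) G <- max(nchar(tbl$position))
  G <- check_G(G)
  n_deep <- sum(nchar(tbl$position) > G)
  if (n_deep > 0) {
    if (!quiet) message(sprintf("dropped %d row(s) deeper than G = %d", n_deep, G))
    tbl <- tbl[nchar(tbl$position) <= G, ]
  }
  pos <- lineage_positions(G)
  # canonical pedigree order: numeric when ids are numeric-like, else lexical
  ids <- unique(tbl$pedigree)
  ids_num <- suppressWarnings(as.numeric(ids))
  ids <- if (!anyNA(ids_num)) ids[order(ids_num)] else sort(ids)
  full <- tidyr::expand_grid(pedigree = ids, position = pos) |>
    dplyr::left_join(tbl, by = c("pedigree", "position"))
  if (!quiet) {
    miss <- full |>
      dplyr::group_by(g = nchar(.data$position)) |>
      dplyr::summarise(frac = mean(is.na(.data$value)), .groups = "drop")
    message(sprintf(
      "%d pedigree(s), G = %d; missing fraction by generation: %s",
      dplyr::n_distinct(full$pedigree), G,
      paste(sprintf("g%d: %.0f%%", miss$g, 100 * miss$frac), collapse = ", ")))
  }
  structure(full, G = G)
}

#' Pedigree table depth
#' @param data a pedigree table.
#' @return the analysis depth `G`.
#' @export
pedigree_depth <- function(data) {
  G <- attr(data, "G")
  if (is.null(G)) G <- max(nchar(data$position))
  check_G(G)
}

#' Convert a pedigree table to an n x p trait matrix
#'
#' Rows are pedigrees, columns are lineal positions in canonical order;
#' missing cells are `NA`.
#'
#' @param data a pedigree table (long format).
#' @param G analysis depth (defaults to the table's depth).
#' @return numeric matrix with pedigree rownames and position colnames.
#' @export
trait_matrix <- function(data, G = NULL) {
  if (is.null(G)) G <- pedigree_depth(data)
  tbl <- as_pedigree_table(data, G = G, quiet = TRUE)
  pos <- lineage_positions(G)
  wide <- tidyr::pivot_wider(tbl, names_from = "position",
                             values_from = "value")
  Y <- as.matrix(wide[, pos, drop = FALSE])
  rownames(Y) <- as.character(wide$pedigree)
  Y
}

## ---- file I/O ------------------------------------------------------------

#' Read and write pedigree tables as CSV
#'
#' The canonical on-disk format is long-format delimited text with a header:
#' one row per observed cell, columns for pedigree id, position label and
#' trait value. `read_pedigrees()` validates labels and duplicates with
#' row-numbered messages, pads to the complete `G`-generation layout, and
#' logs a summary. `write_pedigrees()` writes observed and missing rows
#' (missing as empty fields) so the round-trip is exact.
#'
#' @param path file path.
#' @param G analysis depth; defaults to the deepest generation in the file.
#' @param pedigree_col,position_col,value_col column names.
#' @param missing_token additional string(s) interpreted as missing.
#' @param quiet suppress the summary message.
#' @return a pedigree table tibble (see [as_pedigree_table()]).
#' @export
read_pedigrees <- function(path, G = NULL,
                           pedigree_col = "pedigree",
                           position_col = "position",
                           value_col = "value",
                           missing_token = c("", "NA"),
                           quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = missing_token, progress = FALSE)
  if (nrow(raw) == 0) stop(sprintf("empty pedigree file: %s", path), call. = FALSE)
  as_pedigree_table(raw, G = G, pedigree_col = pedigree_col,
                    position_col = position_col, value_col = value_col,
                    quiet = quiet)
}

#' @rdname read_pedigrees
#' @param data a pedigree table.
#' @export
write_pedigrees <- function(data, path) {
  tbl <- as_pedigree_table(data, quiet = TRUE)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Export pedigrees as Newick trees
#'
#' Writes one Newick line per pedigree: the complete binary topology with
#' position labels as node names and trait values attached as node comments
#' (`[&value=...]`; omitted for missing cells). Provided for
#' interoperability with tree viewers; the canonical format is the long CSV.
#'
#' @param data a pedigree table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(data, path) {
  tbl <- as_pedigree_table(data, quiet = TRUE)
  G <- pedigree_depth(tbl)
  lines <- vapply(split(tbl, tbl$pedigree), function(ped) {
    vals <- stats::setNames(ped$value, ped$position)
    rec <- function(label) {
      com <- if (is.na(vals[[label]])) "" else
        sprintf("[&value=%.15g]", vals[[label]])
      if (nchar(label) == G) return(paste0(label, com))
      paste0("(", rec(paste0(label, "0")), ",", rec(paste0(label, "1")), ")",
             label, com)
    }
    paste0(rec("1"), ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
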