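#' Construct a validated study-design table
#'
#' Encodes the nested sampling structure: libraries are pooled biological
#' replicates (pools of individuals), two per site, with sites classified into
#' one of two invasion categories (`ancient` or `recent`). One row per
#' sequencing library.
#'
#' Validation enforces the structural invariants the analysis relies on:
#' unique library ids, at most one library per (species, site, pool_index),
#' each site mapped to exactly one invasion category, and
#' `pool_size == n_males + n_females >= 1`.
#'
#' @param df data.frame with columns `library_id`, `species`, `site`,
#'   `invasion_category`, `pool_index`, `pool_size`, `n_males`, `n_females`.
#' @return A `study_design` data.frame (row order preserved).
#' @export
study_design <- function(df) {
  needed <- c("library_id", "species", "site", "invasion_category",
              "pool_index", "pool_size", "n_males", "n_females")
  if (!all(needed %in% names(df)))
    format_error(paste("design table missing columns:",
                       paste(setdiff(needed, names(df)), collapse = ", ")))
  df <- as.data.frame(df)[, needed]
  df$library_id <- as.character(df$library_id)
  df$species <- as.character(df$species)
  df$site <- as.character(df$site)
  df$invasion_category <- as.character(df$invasion_category)
  for (col in c("pool_index", "pool_size", "n_males", "n_females")) {
    v <- df[[col]]
    if (anyNA(v) || !is.numeric(v) || any(v != round(v)))
      format_error(sprintf("column %s must be integral", col))
    df[[col]] <- as.integer(v)
  }
  if (anyDuplicated(df$library_id))
    format_error("duplicated library_id in design")
  if (!all(df$invasion_category %in% c("ancient", "recent")))
    format_error("invasion_category must be 'ancient' or 'recent'")
  if (!all(df$pool_index %in% c(1L, 2L)))
    format_error("pool_index must be 1 or 2")
  key <- paste(df$species, df$site, df$pool_index)
  if (anyDuplicated(key))
    consistency_error("duplicated (species, site, pool_index) in design")
  site_cat <- unique(df[, c("site", "invasion_category")])
  if (anyDuplicated(site_cat$site))
    consistency_error("a site is mapped to more than one invasion category")
  if (any(df$pool_size < 1L))
    format_error("pool_size must be >= 1")
  if (any(df$pool_size != df$n_males + df$n_females))
    consistency_error("pool_size must equal n_males + n_females")
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d libraries, %d sites (%d ancient, %d recent), species: %s\n",
              nrow(x), length(unique(x$site)),
              length(unique(x$site[x$invasion_category == "ancient"])),
              length(unique(x$site[x$invasion_category == "recent"])),
              paste(unique(x$species), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a study-design table from a tab-separated file
#' @param path path to a TSV file with the eight design columns.
#' @return A [study_design()] in file order.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  study_design(df)
}

#' Write a study-design table
#' @param design a [study_design()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Libraries of one species, site-ordered; internal convenience.
design_species <- function(design, species = NULL) {
  if (!is.null(species)) design <- design[design$species == species, , drop = FALSE]
  if (length(unique(design$species)) > 1L)
    design_error("analysis requires a single-species design; subset first")
  design
}
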