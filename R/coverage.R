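#' Completeness of gene sets against a single-copy reference
#'
#' The fraction of reference single-copy orthologs detected in a query gene
#' set (genome or EST-derived) approximates its completeness. Detection
#' itself (similarity-search assignment of query sequences to groups) is
#' upstream of this package; this consumes precomputed assignments.
#'
#' @param assignments data frame with columns `species` and `group_id`: the
#'   reference groups detected in each query species. Repeated entries are
#'   collapsed (set semantics).
#' @param reference character vector of reference single-copy group ids.
#' @param species optional character vector of species to report (species
#'   with no assignments get 0%); default: species present in `assignments`.
#' @return a `coverage_report`: data frame with `species`, `n_found`,
#'   `n_missing`, `percent_found` (one decimal, matching the conventional
#'   presentation) and a `mean_percent` attribute.
#' @export
#' @examples
#' a <- data.frame(species = "human", group_id = paste0("g", 1:1124))
#' completeness(a, paste0("g", 1:1126))
completeness <- function(assignments, reference, species = NULL) {
  stopifnot(is.data.frame(assignments),
            all(c("species", "group_id") %in% names(assignments)))
  if (length(reference) == 0L) stop("reference set is empty", call. = FALSE)
  reference <- unique(as.character(reference))
  unknown <- setdiff(unique(assignments$group_id), reference)
  if (length(unknown)) {
    stop("assignments reference unknown group id(s): ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  if (is.null(species)) species <- sort(unique(assignments$species))
  by_sp <- split(assignments$group_id, assignments$species)
  n_found <- vapply(species, function(s) {
    length(unique(by_sp[[s]]))
  }, integer(1))
  df <- data.frame(species = species,
                   n_found = n_found,
                   n_missing = length(reference) - n_found,
                   percent_found = round(100 * n_found / length(reference), 1),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(df, class = c("coverage_report", "data.frame"),
            reference_size = length(reference),
            mean_percent = round(mean(df$percent_found), 1))
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage against", attr(x, "reference_size"),
      "reference single-copy orthologs\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean coverage: %.1f%%\n", attr(x, "mean_percent")))
  invisible(x)
}

#' Saturation series of found orthologs versus dataset size
#'
#' Orders (dataset size, orthologs found) pairs by size for plotting the
#' found-count saturation; no transformation beyond ordering is applied.
#'
#' @param sizes numeric vector of dataset sizes (e.g. number of ESTs).
#' @param n_found integer vector of reference orthologs found, same length.
#' @return data frame sorted by `size`.
#' @export
saturation_curve <- function(sizes, n_found) {
  stopifnot(length(sizes) == length(n_found), length(sizes) >= 1L)
  df <- data.frame(size = sizes, n_found = n_found)
  df[order(df$size), , drop = FALSE]
}

#' Read a species/group assignment table
#'
#' TSV with columns `species <TAB> group_id` (header expected).
#'
#' @param file path.
#' @return data frame with columns `species`, `group_id`.
#' @export
read_assignments <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("species", "group_id") %in% names(df))) {
    names(df)[1:2] <- c("species", "group_id")
  }
  df[, c("species", "group_id")]
}
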