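#' Ortholog copy-number table
#'
#' Construct the species-by-family integer copy-number matrix used as input
#' to fitting, reconstruction and evaluation. Rows are species (genomes),
#' columns are gene families (ortholog groups).
#'
#' @param counts integer matrix of nonnegative copy numbers with species as
#'   rows; must carry unique row (species) and column (family) names.
#' @return an integer matrix of class \code{gcevo_table}.
#' @export
ortholog_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have species row names and family column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate species labels")
  if (anyDuplicated(colnames(counts))) stop("duplicate family labels")
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("copy numbers must be nonnegative integers; offending cell: family '%s', species '%s'",
                 colnames(counts)[bad[2L]], rownames(counts)[bad[1L]]))
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("gcevo_table", "matrix", "array")
  counts
}

#' Read a tab-delimited ortholog table
#'
#' The on-disk layout is CAFE-style: a header row
#' \code{FamilyID<TAB>species1<TAB>...<TAB>speciesN} followed by one row per
#' gene family with integer copy numbers. Internally the matrix is stored
#' species-by-family.
#'
#' @param path path to the TSV file.
#' @return a [ortholog_table()] matrix (species x families).
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("ortholog table needs a FamilyID column plus at least one species")
  fams <- df[[1L]]
  species <- colnames(df)[-1L]
  if (anyDuplicated(fams)) stop("duplicate family labels in ", path)
  if (anyDuplicated(species)) stop("duplicate species labels in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative copy number at family '%s', species '%s'",
                 fams[bad[1L, 1L]], species[bad[1L, 2L]]))
  }
  counts <- t(num)
  dimnames(counts) <- list(species, fams)
  ortholog_table(counts)
}

#' Write an ortholog table to TSV
#'
#' @param table a [ortholog_table()] matrix.
#' @param path output path.
#' @export
write_ortholog_table <- function(table, path) {
  df <- data.frame(FamilyID = colnames(table),
                   t(unclass(table)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Clip copy numbers at a maximum
#'
#' Families with more than \code{lmax} copies in some genome are treated as
#' having exactly \code{lmax} copies, so the evolutionary model operates on
#' the finite state space \code{0..lmax}.
#'
#' @param table a [ortholog_table()] matrix.
#' @param lmax positive integer truncation bound.
#' @return the clipped table; the number of clipped cells is reported via
#'   \code{message()}.
#' @export
clip_copy_numbers <- function(table, lmax) {
  if (!is.numeric(lmax) || length(lmax) != 1L || lmax < 1 || lmax != round(lmax)) {
    stop("'lmax' must be a positive integer")
  }
  n_clip <- sum(table > lmax)
  if (n_clip > 0L) {
    message(n_clip, " cells clipped to lmax = ", lmax)
    table[table > lmax] <- as.integer(lmax)
  }
  table
}

#' Align an ortholog table with a tree
#'
#' Reorders the table rows to the tree's leaf order and verifies that the two
#' species sets are identical; species present in only one input are a hard
#' error (dataset curation is assumed to have happened upstream).
#'
#' @param table a [ortholog_table()] matrix.
#' @param tree a [as_gcevo_tree()] tree.
#' @return the table with rows in tree leaf order.
#' @export
align_table_tree <- function(table, tree) {
  sp_table <- rownames(table)
  sp_tree <- tip_labels(tree)
  only_tab <- setdiff(sp_table, sp_tree)
  only_tree <- setdiff(sp_tree, sp_table)
  if (length(only_tab) || length(only_tree)) {
    stop("species sets of table and tree differ; only in table: {",
         paste(utils::head(only_tab, 5L), collapse = ", "),
         "}, only in tree: {",
         paste(utils::head(only_tree, 5L), collapse = ", "), "}")
  }
  out <- table[sp_tree, , drop = FALSE]
  class(out) <- c("gcevo_table", "matrix", "array")
  out
}
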