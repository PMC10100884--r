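#' Validate an ASV count table
#'
#' The canonical community object throughout the package is a numeric matrix
#' with samples as rows and ASVs as columns, both dimensions named with
#' unique identifiers and all entries nonnegative integers.
#'
#' @param x matrix to validate.
#' @return the validated matrix (counts coerced to integer storage).
#' @keywords internal
validate_asv_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("ASV table must be a numeric matrix (samples x ASVs)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("ASV table must have sample row names and ASV column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate identifier: sample ids must be unique")
  if (anyDuplicated(colnames(x)))
    stop("duplicate identifier: ASV ids must be unique")
  if (anyNA(x) || any(x < 0)) stop("negative count or missing value in ASV table")
  if (any(abs(x - round(x)) > 1e-8)) stop("non-integer count in ASV table")
  storage.mode(x) <- "integer"
  x
}

#' Read an ASV count table from a tab-separated file
#'
#' @param path path to a TSV file with a header row and identifiers in the
#'   first column.
#' @param samples_as whether samples are the rows or the columns of the file;
#'   the returned matrix is always samples x ASVs.
#' @return validated integer matrix, samples x ASVs.
#' @export
read_asv_table <- function(path, samples_as = c("rows", "columns")) {
  samples_as <- match.arg(samples_as)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate identifier in first column of ", path)
  body <- raw[, -1, drop = FALSE]
  if (anyDuplicated(names(body))) stop("duplicate identifier in header of ", path)
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric entries in column(s): ", paste(names(body)[!num], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  if (samples_as == "columns") m <- t(m)
  validate_asv_table(m)
}

#' Read sample metadata (region, coordinates, environmental variables)
#'
#' @param path TSV with columns `sample_id`, `region`, `lat`, `lon` and the
#'   environmental variables.
#' @param env_columns character vector naming the environmental variables
#'   that must be present.
#' @return data.frame keyed by `sample_id` (also the row names), carrying the
#'   attribute `env_columns`.
#' @export
read_metadata <- function(path, env_columns) {
  meta <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "region", "lat", "lon", env_columns)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(meta$lat < -90 | meta$lat > 90, na.rm = FALSE) || anyNA(meta$lat))
    stop("lat out of range [-90, 90]")
  if (any(meta$lon < -180 | meta$lon > 180) || anyNA(meta$lon))
    stop("lon out of range [-180, 180]")
  rownames(meta) <- meta$sample_id
  attr(meta, "env_columns") <- env_columns
  meta
}

#' Read a taxonomy map
#'
#' @param path TSV with columns `asv_id`, `group`, `lineage`, `genus`,
#'   `species` (the last two may be "unknown").
#' @return data.frame keyed by `asv_id`.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("asv_id", "group", "lineage")
  missing <- setdiff(required, names(tax))
  if (length(missing))
    stop("taxonomy missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tax$asv_id)) stop("duplicate asv_id in taxonomy")
  if (any(!nzchar(tax$lineage)) || anyNA(tax$lineage))
    stop("empty lineage label in taxonomy")
  rownames(tax) <- tax$asv_id
  tax
}

#' Remove singleton ASVs
#'
#' A singleton is an ASV whose total count summed over all samples equals 1;
#' such ASVs are dropped, all samples are kept. Idempotent.
#'
#' @param t ASV table (samples x ASVs).
#' @return table with singleton columns removed.
#' @export
filter_singletons <- function(t) {
  t <- validate_asv_table(t)
  keep <- colSums(t) >= 2L
  if (!any(keep)) stop("empty table after filtering: all ASVs are singletons")
  t[, keep, drop = FALSE]
}

#' Rarefy an ASV table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) down to a common depth, so every
#' row of the result sums to `depth`.
#'
#' @param t ASV table.
#' @param depth target reads per sample, or `"min"` for the smallest row sum.
#' @param seed integer seed; mandatory so the draw is reproducible.
#' @return rarefied integer table with all row sums equal to `depth`.
#' @export
rarefy_table <- function(t, depth = "min", seed) {
  t <- validate_asv_table(t)
  if (missing(seed)) stop("rarefy_table requires an explicit seed")
  rs <- rowSums(t)
  if (identical(depth, "min")) depth <- min(rs)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  low <- rs < depth
  if (any(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(rownames(t)[low], collapse = ", "))
  set.seed(seed)
  # rrarefy's "should be used for observed counts" heuristic misfires on
  # valid tables whose smallest nonzero count exceeds 1; inputs are already
  # validated as integer counts above
  out <- withCallingHandlers(
    vegan::rrarefy(t, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- matrix(as.integer(out), nrow(t), ncol(t), dimnames = dimnames(t))
  validate_asv_table(out)
}

#' Split an ASV table by plankton group
#'
#' @param t ASV table.
#' @param tax taxonomy data.frame from [read_taxonomy()].
#' @param drop_unannotated drop ASVs absent from the taxonomy (with a
#'   message) instead of erroring.
#' @return named list of tables, one per group present in the taxonomy.
#' @export
split_by_group <- function(t, tax, drop_unannotated = FALSE) {
  t <- validate_asv_table(t)
  unknown <- setdiff(colnames(t), tax$asv_id)
  if (length(unknown)) {
    if (!drop_unannotated)
      stop("ASV(s) missing from taxonomy: ", paste(utils::head(unknown, 5), collapse = ", "))
    message("dropping ", length(unknown), " unannotated ASV(s)")
    t <- t[, setdiff(colnames(t), unknown), drop = FALSE]
  }
  groups <- unique(tax$group)
  out <- lapply(groups, function(g) {
    ids <- intersect(colnames(t), tax$asv_id[tax$group == g])
    t[, ids, drop = FALSE]
  })
  names(out) <- groups
  empty <- vapply(out, ncol, integer(1)) == 0L
  if (any(empty))
    warning("group(s) with no ASVs in table: ", paste(groups[empty], collapse = ", "))
  out
}

#' Read a phylogenetic tree from a newick file
#'
#' Missing branch lengths are set to 0 with a warning; duplicate tip labels
#' are an error.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unparseable newick file: ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}
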