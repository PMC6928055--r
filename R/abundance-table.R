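#' Feature-by-sample abundance table
#'
#' The substrate of every analysis stage: a non-negative features x samples
#' matrix of read counts or relative abundances, with unique feature and
#' sample identifiers and an optional taxonomy map (feature id -> ranked
#' lineage string such as `"k__Bacteria;p__Firmicutes;...;g__Roseburia"`).
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param kind `"counts"` (non-negative integers) or `"relative"` (columns
#'   sum to 1 within 1e-8).
#' @param taxonomy optional data frame with columns `feature_id` and
#'   `lineage` (semicolon-separated ranks).
#' @return an `abundance_table` object.
#' @export
abundance_table <- function(values, kind = c("counts", "relative"),
                            taxonomy = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    rlang::abort("`values` needs feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    rlang::abort(paste0("duplicate feature ids: ",
                        paste(unique(rownames(values)[duplicated(rownames(values))]),
                              collapse = ", ")))
  if (anyDuplicated(colnames(values)))
    rlang::abort(paste0("duplicate sample ids: ",
                        paste(unique(colnames(values)[duplicated(colnames(values))]),
                              collapse = ", ")))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    rlang::abort(sprintf("negative abundance at feature '%s', sample '%s'",
                         rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (kind == "relative") {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-8 & cs > 0)
    if (length(bad) > 0)
      rlang::abort(sprintf("relative columns must sum to 1; sample '%s' sums to %g",
                           colnames(values)[bad[1]], cs[bad[1]]))
  }
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    stopifnot(all(c("feature_id", "lineage") %in% names(taxonomy)))
    taxonomy <- taxonomy[match(rownames(values), taxonomy$feature_id), ,
                         drop = FALSE]
    if (anyNA(taxonomy$feature_id))
      rlang::abort("taxonomy is missing entries for some features")
  }
  structure(list(values = values, kind = kind, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table: %d features x %d samples, kind = %s%s>\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @export
as.matrix.abundance_table <- function(x, ...) x$values

#' Long-format view of an abundance table
#'
#' @param x an `abundance_table`.
#' @param ... unused.
#' @return a tibble with columns `feature_id`, `sample_id`, `value` (and
#'   `lineage` when taxonomy is attached).
#' @export
as_tibble.abundance_table <- function(x, ...) {
  out <- tibble::tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id  = rep(colnames(x$values), each = nrow(x$values)),
    value      = as.vector(x$values)
  )
  if (!is.null(x$taxonomy))
    out <- dplyr::left_join(out, x$taxonomy, by = "feature_id")
  out
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Subset an abundance table by features and/or samples
#'
#' @param x an `abundance_table`.
#' @param features,samples character vectors of ids (or logical/integer
#'   indices); `NULL` keeps everything.
#' @return an `abundance_table`. Relative tables are NOT renormalised when
#'   features are dropped; call [to_relative()] if that is wanted.
#' @export
subset_table <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[match(rownames(v), tax$feature_id), ]
  structure(list(values = v, kind = x$kind, taxonomy = tax),
            class = "abundance_table")
}

# ---------------------------------------------------------------------------
# TSV dialect: tab-separated, '#' comment lines, header row, feature id in
# the first column, one column per sample, optional final 'lineage' column.

#' Read an abundance table from TSV
#'
#' @param path file path.
#' @param kind `"counts"` or `"relative"`.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(path, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    rlang::abort(paste0("malformed TSV rows at line(s): ",
                        paste(unique(probs$row), collapse = ", ")))
  has_lineage <- names(df)[ncol(df)] == "lineage"
  tax <- NULL
  if (has_lineage) {
    tax <- tibble::tibble(feature_id = as.character(df[[1]]),
                          lineage = df$lineage)
    df <- df[, -ncol(df)]
  }
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    rlang::abort("non-numeric abundance values")
  if (kind == "counts" && all(vals == round(vals), na.rm = TRUE))
    storage.mode(vals) <- "integer"
  rownames(vals) <- ids
  abundance_table(vals, kind = kind, taxonomy = tax)
}

#' Write an abundance table to TSV
#'
#' Counts round-trip exactly through [read_abundance()].
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @export
write_abundance <- function(table, path) {
  df <- tibble::as_tibble(table$values, rownames = "feature_id")
  if (!is.null(table$taxonomy))
    df$lineage <- table$taxonomy$lineage
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Metadata rows describe samples: `sample_id`, `cohort`, and any of
#' `region`, `sex`, `diet`, `age`, `bmi`. Missing values are permitted and
#' kept as `NA`; `age`/`bmi` must be positive where present.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                        progress = FALSE)
  stopifnot("sample_id" %in% names(df))
  if (anyDuplicated(df$sample_id))
    rlang::abort("duplicate sample ids in metadata")
  for (v in intersect(c("age", "bmi"), names(df))) {
    bad <- which(!is.na(df[[v]]) & df[[v]] <= 0)
    if (length(bad) > 0)
      rlang::abort(sprintf("non-positive %s for sample '%s'", v,
                           df$sample_id[bad[1]]))
  }
  df
}

#' @rdname read_metadata
#' @param meta a metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Rarefy counts to a common depth
#'
#' Each sample is subsampled uniformly WITHOUT replacement (multivariate
#' hypergeometric) to `depth` reads, removing sequencing-depth bias before
#' diversity estimation. The default depth is the minimum column sum, the
#' usual "rarefy to the shallowest sample" policy. Each sample draws from an
#' RNG substream keyed on its id, so results do not depend on column order.
#'
#' @param table a counts `abundance_table`.
#' @param depth target reads per sample; default `min(colSums)`.
#' @param seed integer seed.
#' @return a counts `abundance_table` whose columns all sum to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "counts") rlang::abort("rarefy() needs a counts table")
  v <- table$values
  cs <- colSums(v)
  if (is.null(depth)) depth <- min(cs)
  depth <- as.integer(depth)
  shallow <- which(cs < depth)
  if (length(shallow) > 0)
    rlang::abort(sprintf("sample '%s' has only %d reads (< depth %d)",
                         colnames(v)[shallow[1]], cs[shallow[1]], depth))
  out <- v
  for (j in seq_len(ncol(v))) {
    cj <- v[, j]
    if (cs[j] == depth) next
    sub_seed <- str_seed(colnames(v)[j], seed)
    out[, j] <- with_seed(sub_seed, {
      picked <- sample.int(cs[j], depth)
      tabulate(findInterval(picked - 0.5, c(0, cumsum(cj))), nbins = length(cj))
    })
  }
  abundance_table(out, kind = "counts", taxonomy = table$taxonomy)
}

#' Drop sparse features
#'
#' Removes features whose total read count falls below a fraction of the
#' grand total over all features and samples (default 0.002%), the usual
#' denoising step after OTU clustering.
#'
#' @param table a counts `abundance_table`.
#' @param min_total_fraction minimum feature total as a fraction of the grand
#'   total; default `2e-5` (0.002%).
#' @return filtered `abundance_table`; dropped ids in `attr(, "dropped")`.
#' @export
filter_sparse <- function(table, min_total_fraction = 2e-5) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "counts") rlang::abort("filter_sparse() needs counts")
  tot <- rowSums(table$values)
  cut <- min_total_fraction * sum(tot)
  keep <- tot >= cut
  # threshold 0 keeps everything, including all-zero features
  if (min_total_fraction <= 0) keep[] <- TRUE
  out <- subset_table(table, features = which(keep))
  attr(out, "dropped") <- rownames(table$values)[!keep]
  out
}

#' Convert counts to relative abundances
#'
#' @param table an `abundance_table`.
#' @return a relative `abundance_table` (columns sum to 1).
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  cs <- colSums(v)
  if (any(cs == 0)) rlang::abort("cannot normalise an all-zero sample")
  abundance_table(sweep(v, 2, cs, "/"), kind = "relative",
                  taxonomy = table$taxonomy)
}

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Cumulate abundances at a higher taxonomic rank
#'
#' Sums feature rows sharing the same lineage prefix up to `rank` (e.g. all
#' OTUs of one genus become one genus row). Features whose lineage does not
#' reach `rank` are grouped under their truncated lineage.
#'
#' @param table an `abundance_table` with taxonomy.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return an `abundance_table` whose feature ids are lineage prefixes.
#' @export
collapse_taxa <- function(table, rank = "genus") {
  stopifnot(inherits(table, "abundance_table"))
  rank <- match.arg(rank, .tax_ranks)
  if (is.null(table$taxonomy)) rlang::abort("collapse_taxa() needs taxonomy")
  depth <- match(rank, .tax_ranks)
  prefix <- vapply(strsplit(table$taxonomy$lineage, ";", fixed = TRUE),
                   function(p) paste(head(p, depth), collapse = ";"),
                   character(1))
  if (!any(lengths(strsplit(table$taxonomy$lineage, ";")) >= depth))
    rlang::abort(sprintf("no lineage reaches rank '%s'", rank))
  v <- rowsum(table$values, group = prefix)
  tax <- tibble::tibble(feature_id = rownames(v), lineage = rownames(v))
  abundance_table(v, kind = table$kind, taxonomy = tax)
}

#' Keep features prevalent in every declared group
#'
#' A feature is kept when it is non-zero in at least `min_nonzero_fraction`
#' of the samples of EVERY group (default 51%, i.e. a non-zero median in each
#' cohort). With `groups = NULL` the whole table is one group.
#'
#' @param table an `abundance_table`.
#' @param min_nonzero_fraction fraction in (0, 1]; default 0.51.
#' @param groups optional factor/character vector of group labels, one per
#'   sample (named by sample id or in column order).
#' @return filtered `abundance_table`.
#' @export
prevalence_filter <- function(table, min_nonzero_fraction = 0.51,
                              groups = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (is.null(groups)) groups <- rep("all", ncol(v))
  if (!is.null(names(groups))) groups <- groups[colnames(v)]
  groups <- as.factor(groups)
  keep <- rep(TRUE, nrow(v))
  for (g in levels(groups)) {
    sub <- v[, groups == g, drop = FALSE]
    frac <- rowMeans(sub > 0)
    keep <- keep & (frac >= min_nonzero_fraction)
  }
  subset_table(table, features = which(keep))
}
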