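#' OTU count tables
#'
#' A lightweight samples-by-taxa count container for post-clustering
#' amplicon data: a non-negative integer matrix with sample ids as row
#' names, OTU ids as column names, and one semicolon-separated taxonomy
#' lineage string per taxon (Greengenes-style rank prefixes, e.g.
#' `"k__Bacteria; p__Bacteroidetes; c__Sphingobacteria"`).
#'
#' @param counts samples x taxa matrix of non-negative counts.
#' @param taxonomy character vector of lineage strings, one per taxon.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0L)
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (length(taxonomy) != ncol(counts))
    stop("need one taxonomy string per taxon (column)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, taxonomy = as.character(taxonomy)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa, library sizes %d-%d\n",
              nrow(x$counts), ncol(x$counts),
              as.integer(min(library_sizes(x))), as.integer(max(library_sizes(x)))))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @return `library_sizes()`: named per-sample row sums.
#' @export
library_sizes <- function(x) rowSums(x$counts)

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Remove singleton taxa
#'
#' Drops taxa whose total count across all samples is at most 1, the usual
#' guard against spurious OTUs from sequencing error.
#'
#' @param table an [otu_table()].
#' @return The filtered `otu_table`.
#' @export
exclude_singletons <- function(table) {
  keep <- colSums(table$counts) > 1
  otu_table(table$counts[, keep, drop = FALSE], table$taxonomy[keep])
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (one draw per sample), removing library-size bias before diversity
#' comparisons. Per-sample marginal counts follow the multivariate
#' hypergeometric law. Deterministic given `seed`.
#'
#' @param table an [otu_table()].
#' @param depth target depth; defaults to the minimum library size.
#' @param seed integer seed recorded in the output's `rarefaction`
#'   attribute.
#' @return A rarefied `otu_table` with every library size equal to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  ls <- library_sizes(table)
  if (is.null(depth)) depth <- min(ls)
  if (depth < 1) stop("depth must be at least 1")
  if (any(ls < depth))
    stop("depth exceeds the library size of sample(s): ",
         paste(names(ls)[ls < depth], collapse = ", "))
  # rrarefy's "observed counts" heuristic warns whenever the smallest
  # positive count exceeds 1, which is routine for deep multinomial tables
  counts <- withr::with_seed(seed,
                             suppressWarnings(vegan::rrarefy(table$counts, depth)))
  out <- otu_table(counts, table$taxonomy)
  attr(out, "rarefaction") <- list(depth = depth, seed = seed)
  out
}

#' Relative abundance matrix
#'
#' @param table an [otu_table()] (no zero-sum samples).
#' @return Samples x taxa matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  ls <- library_sizes(table)
  if (any(ls == 0)) stop("zero-sum sample(s): ", paste(names(ls)[ls == 0], collapse = ", "))
  sweep(table$counts, 1, ls, "/")
}

#' Extract one rank from a lineage string
#'
#' @param taxonomy character lineages with semicolon-separated,
#'   prefix-tagged ranks (`k__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__`).
#' @param rank rank name (`"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`).
#' @return Character vector of rank labels; lineages lacking the rank (or
#'   with an empty label) map to `"unclassified"`.
#' @export
taxonomy_rank <- function(taxonomy,
                          rank = c("class", "kingdom", "phylum", "order",
                                   "family", "genus", "species")) {
  rank <- match.arg(rank)
  prefix <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
              family = "f", genus = "g", species = "s")[[rank]]
  pat <- paste0("(^|;)\\s*", prefix, "__([^;]*)")
  m <- regmatches(taxonomy, regexec(pat, taxonomy))
  lab <- vapply(m, function(g) if (length(g) >= 3L) trimws(g[3]) else "", "")
  lab[lab == ""] <- "unclassified"
  lab
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums counts over taxa sharing the same rank label; total counts are
#' conserved. Lineages lacking the rank go to an `"unclassified"` bucket.
#'
#' @inheritParams rarefy
#' @inheritParams taxonomy_rank
#' @return An `otu_table` with one column per rank label.
#' @export
aggregate_rank <- function(table, rank = "class") {
  labs <- taxonomy_rank(table$taxonomy, rank)
  groups <- unique(labs)
  agg <- sapply(groups, function(g)
    rowSums(table$counts[, labs == g, drop = FALSE]))
  if (nrow(table$counts) == 1L) agg <- matrix(agg, nrow = 1L,
                                              dimnames = list(rownames(table$counts), groups))
  out <- otu_table(agg, groups)
  colnames(out$counts) <- groups
  out
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log_base(p_i))` over the positive proportions of one
#' sample's counts. Base 2 by default.
#'
#' @param counts one sample's counts (at least one positive).
#' @param base logarithm base.
#' @return Shannon index `H >= 0`.
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero sample has no defined diversity")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Shannon diversity per sample of a table
#'
#' @inheritParams rarefy
#' @inheritParams shannon
#' @return Named vector of per-sample Shannon indices.
#' @export
shannon_per_sample <- function(table, base = 2) {
  apply(table$counts, 1, shannon, base = base)
}

#' Principal component ordination of a proportion matrix
#'
#' Column-centred PCA on the covariance (not correlation) form, applied to
#' relative-abundance matrices without further transformation. Components
#' are ordered by decreasing explained variance.
#'
#' @param mat samples x features numeric matrix (typically
#'   [relative_abundance()] output, possibly rank-aggregated).
#' @return List of class `ordination_result`: `scores` (samples x
#'   components), `loadings` (features x components), `explained` (variance
#'   fractions), `sdev`.
#' @export
pca_ordination <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 samples for an ordination")
  if (ncol(mat) < 2L) stop("need at least 2 features for an ordination")
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  structure(list(scores = p$x, loadings = p$rotation,
                 explained = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev),
            class = "ordination_result")
}

#' One-way ANOVA of a per-sample value across locations
#'
#' Classical one-way fixed-effects F test: `F = (SSB/df_b) / (SSW/df_w)`,
#' p-value from the F distribution. Groups with fewer than 2 samples are an
#' error; if every group has zero within-group variance but means differ,
#' the p = 0 limit is flagged via `degenerate = TRUE`.
#'
#' @param values numeric per-sample values.
#' @param groups location labels (>= 2 groups, each with >= 2 samples).
#' @return List of class `group_test_result`: `F`, `p`, `df`, `group_means`,
#'   `degenerate`.
#' @export
anova_by_location <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs >= 2 samples; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  means <- tapply(values, groups, mean)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    degenerate <- length(unique(means)) > 1L
    return(structure(list(F = if (degenerate) Inf else 0,
                          p = if (degenerate) 0 else 1,
                          df = c(nlevels(groups) - 1L, length(values) - nlevels(groups)),
                          group_means = means, degenerate = TRUE),
                     class = "group_test_result"))
  }
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  structure(list(F = unname(ow$statistic), p = ow$p.value,
                 df = unname(ow$parameter), group_means = means,
                 degenerate = FALSE),
            class = "group_test_result")
}

#' Per-taxon ANOVA across locations
#'
#' Runs [anova_by_location()] on every column of a proportion matrix.
#'
#' @param mat samples x taxa proportion matrix.
#' @param groups location labels per sample.
#' @return Data frame with one row per taxon: `taxon`, `F`, `p`.
#' @export
anova_per_taxon <- function(mat, groups) {
  res <- lapply(colnames(mat), function(tx) {
    a <- anova_by_location(mat[, tx], groups)
    data.frame(taxon = tx, F = a$F, p = a$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Taxon-geochemistry correlation matrix
#'
#' Pearson r and two-sided p for every (taxon, geochemical variable) pair,
#' via [pearson_test()]. Raw p-values by default; Benjamini-Hochberg
#' adjusted values are reported alongside when `adjust = TRUE`. Constant
#' variables are flagged as undefined rather than erroring.
#'
#' @param proportions samples x taxa proportion matrix.
#' @param geochem samples x variables data frame or matrix, rows matched to
#'   `proportions`.
#' @param adjust report BH-adjusted p-values as well (default `FALSE`).
#' @return Data frame with columns `taxon`, `variable`, `r`, `p`,
#'   `defined`, and `p_adj` when `adjust = TRUE`.
#' @export
taxon_geochem_correlations <- function(proportions, geochem, adjust = FALSE) {
  geochem <- as.data.frame(geochem)
  if (nrow(geochem) != nrow(proportions))
    stop("proportions and geochemistry must cover the same samples")
  grid <- expand.grid(taxon = colnames(proportions), variable = names(geochem),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- proportions[, grid$taxon[i]]
    y <- geochem[[grid$variable[i]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(grid[i, ], r = NA_real_, p = NA_real_, defined = FALSE))
    ct <- pearson_test(x, y)
    data.frame(grid[i, ], r = ct$r, p = ct$p, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
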