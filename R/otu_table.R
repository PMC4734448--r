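#' Construct an OTU table
#'
#' A samples-by-OTUs count table with per-OTU annotations: a 7-rank taxonomy
#' string, a 16S rRNA gene copy number, and a domain label
#' (`"prokaryote"`/`"eukaryote"`).
#'
#' @param counts Non-negative numeric matrix, samples in rows, OTUs in
#'   columns, with dimnames.
#' @param taxonomy Named character vector (per OTU).
#' @param copy_number Named positive numeric vector (per OTU).
#' @param domain Named character vector (per OTU), values `"prokaryote"` or
#'   `"eukaryote"`. Default: all prokaryote.
#' @return An object of class `"otu_tab"`.
#' @export
otu_tab <- function(counts, taxonomy, copy_number = NULL, domain = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and OTU colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  otus <- colnames(counts)
  if (is.null(copy_number)) copy_number <- stats::setNames(rep(1, length(otus)), otus)
  if (is.null(domain)) domain <- stats::setNames(rep("prokaryote", length(otus)), otus)
  if (!all(otus %in% names(taxonomy))) stop("taxonomy missing for some OTUs")
  if (!all(otus %in% names(copy_number))) stop("copy_number missing for some OTUs")
  if (any(copy_number[otus] <= 0)) stop("copy numbers must be positive")
  if (!all(domain[otus] %in% c("prokaryote", "eukaryote")))
    stop("domain must be 'prokaryote' or 'eukaryote'")
  structure(list(counts = counts, taxonomy = taxonomy[otus],
                 copy_number = copy_number[otus], domain = domain[otus]),
            class = "otu_tab")
}

#' @export
print.otu_tab <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs (%d prokaryote, %d eukaryote), total %d reads\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$domain == "prokaryote"), sum(x$domain == "eukaryote"),
              as.integer(round(sum(x$counts)))))
  invisible(x)
}

#' Row-wise relative abundance
#'
#' @param x An `otu_tab` or a counts matrix.
#' @return Matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_tab")) x$counts else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("all-zero sample row")
  sweep(m, 1, tot, "/")
}

#' Restrict an OTU table to one domain
#'
#' @param x An `otu_tab`.
#' @param domain `"prokaryote"` (default) or `"eukaryote"`.
#' @return An `otu_tab` with only the matching OTUs.
#' @export
subset_domain <- function(x, domain = "prokaryote") {
  stopifnot(inherits(x, "otu_tab"))
  keep <- names(x$domain)[x$domain == domain]
  otu_tab(x$counts[, keep, drop = FALSE], x$taxonomy[keep],
          x$copy_number[keep], x$domain[keep])
}

#' Extract one taxonomy rank from an OTU table
#'
#' Taxonomy strings use the greengenes-style
#' `k__; p__; c__; o__; f__; g__; s__` convention.
#'
#' @param x An `otu_tab`.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return Named character vector per OTU.
#' @export
taxonomy_rank <- function(x, rank = "order") {
  ranks <- c(kingdom = 1, phylum = 2, class = 3, order = 4, family = 5,
             genus = 6, species = 7)
  i <- ranks[[match.arg(rank, names(ranks))]]
  parts <- strsplit(x$taxonomy, ";\\s*")
  out <- vapply(parts, function(p) if (length(p) >= i) sub("^[a-z]__", "", p[i]) else NA_character_,
                character(1))
  stats::setNames(out, names(x$taxonomy))
}

#' Write / read an OTU table as TSV
#'
#' The TSV has one row per OTU: `otu_id`, `taxonomy`, `copy_number`,
#' `domain`, then one count column per sample.
#'
#' @param x An `otu_tab`.
#' @param path File path.
#' @return `read_otu_tsv` returns an `otu_tab`.
#' @export
write_otu_tsv <- function(x, path) {
  stopifnot(inherits(x, "otu_tab"))
  df <- data.frame(otu_id = colnames(x$counts), taxonomy = x$taxonomy,
                   copy_number = x$copy_number, domain = x$domain,
                   t(x$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("otu_id", "taxonomy", "copy_number", "domain")
  samples <- setdiff(names(df), meta)
  counts <- t(as.matrix(df[, samples, drop = FALSE]))
  colnames(counts) <- df$otu_id
  otu_tab(counts,
          stats::setNames(df$taxonomy, df$otu_id),
          stats::setNames(df$copy_number, df$otu_id),
          stats::setNames(df$domain, df$otu_id))
}

#' Write / read an OTU table in BIOM-JSON format
#'
#' Uses the Bioconductor biomformat package. Taxonomy, copy number and
#' domain ride along as observation metadata.
#'
#' @param x An `otu_tab`.
#' @param path File path (`.biom`).
#' @return `read_otu_biom` returns an `otu_tab`.
#' @export
write_otu_biom <- function(x, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM output")
  obs_meta <- data.frame(taxonomy = x$taxonomy,
                         copy_number = x$copy_number,
                         domain = x$domain,
                         row.names = colnames(x$counts),
                         stringsAsFactors = FALSE)
  b <- biomformat::make_biom(data = t(x$counts),
                             observation_metadata = obs_meta)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' @rdname write_otu_biom
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM input")
  b <- biomformat::read_biom(path)
  counts <- t(as(biomformat::biom_data(b), "matrix"))
  om <- as.data.frame(biomformat::observation_metadata(b),
                      stringsAsFactors = FALSE)
  # BIOM-JSON round trips drop metadata column names; fall back to position
  # (taxonomy, copy_number, domain as written by write_otu_biom)
  if (!all(c("taxonomy", "copy_number", "domain") %in% names(om)))
    names(om)[1:3] <- c("taxonomy", "copy_number", "domain")
  otus <- colnames(counts)
  om <- om[otus, , drop = FALSE]
  otu_tab(counts,
          stats::setNames(as.character(om$taxonomy), otus),
          stats::setNames(as.numeric(om$copy_number), otus),
          stats::setNames(as.character(om$domain), otus))
}
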