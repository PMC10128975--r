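#' Construct a canonical undirected edge list
#'
#' Edges are stored with `from < to` lexicographically, self-loops removed
#' and duplicates collapsed. When a weighted pair appears more than once,
#' the maximum weight is kept, so the result does not depend on input order.
#'
#' @param from,to Character vectors of gene identifiers.
#' @param weight Optional numeric vector of non-negative edge weights.
#' @return A data frame of class `edge_list` with columns `from`, `to` and,
#'   when weighted, `weight`, sorted by `(from, to)`.
#' @export
edge_list <- function(from, to, weight = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have the same length")
  }
  if (!is.null(weight)) {
    weight <- as.numeric(weight)
    if (length(weight) != length(from)) {
      stop("'weight' must match the number of edges")
    }
    if (any(!is.finite(weight))) stop("edge weights must be finite")
    if (any(weight < 0)) stop("edge weights must be >= 0")
  }
  keep <- from != to  # self-loops carry no interaction information
  from <- from[keep]
  to <- to[keep]
  if (!is.null(weight)) weight <- weight[keep]
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- weight
  if (nrow(df) > 0L) {
    if (is.null(weight)) {
      df <- unique(df)
    } else {
      key <- paste(df$from, df$to, sep = "\r")
      w <- tapply(df$weight, key, max)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$weight <- as.numeric(w[paste(df$from, df$to, sep = "\r")])
    }
    df <- df[order(df$from, df$to), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Read an undirected edge list from a TSV file
#'
#' Expects two columns (`geneA`, `geneB`) or, with `weighted = TRUE`, a
#' third numeric weight column. A header line in a weighted file is
#' detected by its non-numeric third field and skipped. Edges are
#' canonicalized via [edge_list()].
#'
#' @param path Path to a tab- or space-separated file.
#' @param weighted Logical; whether a third weight column is required.
#' @return An `edge_list`.
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(edge_list(character(), character(),
                     weight = if (weighted) numeric()))
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  need <- if (weighted) 3L else 2L
  short <- which(lengths(parts) < need)
  if (length(short) > 0L) {
    stop(sprintf("malformed line %d in '%s': expected %d columns",
                 line_no[short[1L]], path, need))
  }
  a <- vapply(parts, `[[`, character(1L), 1L)
  b <- vapply(parts, `[[`, character(1L), 2L)
  if (!weighted) {
    return(edge_list(a, b))
  }
  w_chr <- vapply(parts, `[[`, character(1L), 3L)
  w <- suppressWarnings(as.numeric(w_chr))
  if (is.na(w[1L]) && (length(w) == 1L || !anyNA(w[-1L]))) {
    a <- a[-1L]
    b <- b[-1L]
    w <- w[-1L]
    line_no <- line_no[-1L]
  }
  bad <- which(is.na(w))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in '%s': non-numeric weight",
                 line_no[bad[1L]], path))
  }
  neg <- which(w < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative weight at line %d in '%s'",
                 line_no[neg[1L]], path))
  }
  edge_list(a, b, weight = w)
}

#' Write an edge list to a TSV file
#'
#' @param edges An `edge_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an annotation collection
#'
#' @param sets Named list of character vectors (gene sets); every set must
#'   be non-empty and names unique.
#' @param descriptions Optional named character vector of set descriptions.
#' @param namespace Single label for the collection (e.g. `"GO-BP"`).
#' @return A list of class `annotation_collection` with elements `sets`,
#'   `descriptions` and `namespace`.
#' @export
annotation_collection <- function(sets, descriptions = NULL,
                                  namespace = "annotations") {
  if (length(sets) > 0L && (is.null(names(sets)) || anyNA(names(sets)) ||
                            any(!nzchar(names(sets))))) {
    stop("annotation sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate annotation id: ",
         names(sets)[anyDuplicated(names(sets))])
  }
  if (any(lengths(sets) == 0L)) stop("annotation sets must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 namespace = namespace),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("annotation_collection '%s': %d sets, %d distinct genes\n",
              x$namespace, length(x$sets),
              length(unique(unlist(x$sets, use.names = FALSE)))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: `id <tab> description <tab> gene1 <tab> gene2 ...`.
#' Lines with no genes or duplicated ids are rejected.
#'
#' @param path Path to a GMT file.
#' @param namespace Label attached to the collection.
#' @return An [annotation_collection()].
#' @export
read_gmt <- function(path, namespace = "annotations") {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d in '%s' has no genes",
                 line_no[short[1L]], path))
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate annotation id in '", path, "': ",
         ids[anyDuplicated(ids)])
  }
  desc <- stats::setNames(vapply(parts, `[[`, character(1L), 2L), ids)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  annotation_collection(sets, desc, namespace = namespace)
}

#' Write an annotation collection in GMT format
#'
#' @param annotations An [annotation_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations$sets), function(id) {
    paste(c(id, annotations$descriptions[[id]], annotations$sets[[id]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read subject phenotype labels
#'
#' Two tab-separated columns: subject id and a label, `healthy` or
#' `diseased` (case-insensitive).
#'
#' @param path Path to the phenotype TSV.
#' @return Named character vector mapping subject id to `"healthy"` or
#'   `"diseased"`, in file order.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("subject", "label"),
                          colClasses = "character")
  if (anyDuplicated(df$subject)) {
    stop("duplicate subject id: ", df$subject[anyDuplicated(df$subject)])
  }
  lab <- tolower(df$label)
  bad <- !(lab %in% c("healthy", "diseased"))
  if (any(bad)) {
    stop("unknown phenotype label '", df$label[which(bad)[1L]],
         "' (expected healthy/diseased)")
  }
  stats::setNames(lab, df$subject)
}

#' Construct a subject-by-gene variant profile
#'
#' @param entries Binary matrix (subjects in rows, genes in columns) with
#'   row and column names.
#' @param phenotypes Optional named character vector
#'   (`"healthy"`/`"diseased"`) covering every subject.
#' @return A list of class `variant_profile` with elements `M`,
#'   `subjects`, `genes`, `phenotypes`.
#' @export
variant_profile <- function(entries, phenotypes = NULL) {
  entries <- as.matrix(entries)
  if (is.null(rownames(entries)) || is.null(colnames(entries))) {
    stop("variant matrix needs subject row names and gene column names")
  }
  if (!all(entries %in% c(0, 1))) {
    stop("variant matrix entries must be 0/1")
  }
  storage.mode(entries) <- "double"
  if (!is.null(phenotypes)) {
    missing <- setdiff(rownames(entries), names(phenotypes))
    if (length(missing) > 0L) {
      stop("missing phenotype for subject: ", missing[1L])
    }
    phenotypes <- phenotypes[rownames(entries)]
    if (!all(phenotypes %in% c("healthy", "diseased"))) {
      stop("phenotype labels must be healthy/diseased")
    }
  }
  structure(list(M = entries,
                 subjects = rownames(entries),
                 genes = colnames(entries),
                 phenotypes = phenotypes),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf("variant_profile: %d subjects x %d genes, %d entries set",
              nrow(x$M), ncol(x$M), sum(x$M)), "\n")
  if (!is.null(x$phenotypes)) {
    cat(sprintf("  phenotypes: %d healthy, %d diseased\n",
                sum(x$phenotypes == "healthy"),
                sum(x$phenotypes == "diseased")))
  }
  invisible(x)
}

#' Read a binary variant-profile matrix from TSV
#'
#' Subjects in rows, genes in columns, a header row of gene names and a
#' first column of subject ids; entries 0/1.
#'
#' @param path Path to the matrix TSV.
#' @param phenotypes Optional named phenotype vector to attach.
#' @return A [variant_profile()].
#' @export
read_variant_matrix <- function(path, phenotypes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  variant_profile(as.matrix(df), phenotypes = phenotypes)
}

#' Write a variant-profile matrix to TSV
#'
#' @param vp A [variant_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_matrix <- function(vp, path) {
  m <- vp$M
  storage.mode(m) <- "integer"
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write per-gene and per-cluster result tables plus run metadata
#'
#' Produces three files under `dir`: `gene_clusters.tsv` (gene, cluster),
#' `cluster_summary.tsv` (per cluster: size, edge count, specificity
#' percentages, number of significant annotations) and
#' `run_metadata.json`.
#'
#' @param clustering A [gene_clustering()].
#' @param subnetworks List of [extract_subnetwork()] results indexed by
#'   cluster.
#' @param enrichment Data frame from [enrich_clusters()] (may have zero
#'   rows).
#' @param labels Specificity labels from [classify_gene_specificity()].
#' @param dir Output directory (created if absent).
#' @param metadata Named list written as JSON (config, seed, objective
#'   trace, ...).
#' @return Character vector of the files written, invisibly.
#' @export
write_cluster_report <- function(clustering, subnetworks, enrichment,
                                 labels, dir, metadata = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes_path <- file.path(dir, "gene_clusters.tsv")
  assign_df <- data.frame(gene = names(clustering$assignment),
                          cluster = unname(clustering$assignment),
                          stringsAsFactors = FALSE)
  utils::write.table(assign_df, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  spec <- summarize_specificity(clustering, labels)
  n_sig <- integer(clustering$k)
  if (nrow(enrichment) > 0L) {
    sig <- enrichment[enrichment$significant, , drop = FALSE]
    tab <- table(factor(sig$cluster_id, levels = seq_len(clustering$k)))
    n_sig <- as.integer(tab)
  }
  edge_counts <- vapply(seq_len(clustering$k), function(k) {
    if (k <= length(subnetworks) && !is.null(subnetworks[[k]])) {
      nrow(subnetworks[[k]]$edges)
    } else 0L
  }, integer(1L))
  summary_df <- data.frame(cluster_id = spec$cluster_id,
                           size = spec$size,
                           n_edges = edge_counts,
                           pct_healthy_specific = spec$pct_healthy_specific,
                           pct_disease_specific = spec$pct_disease_specific,
                           n_enriched_annotations = n_sig,
                           stringsAsFactors = FALSE)
  summary_path <- file.path(dir, "cluster_summary.tsv")
  utils::write.table(summary_df, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  meta_path <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(metadata, meta_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(genes_path, summary_path, meta_path))
}
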