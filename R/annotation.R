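## Target -> adverse-effect -> organ annotation knowledge layer:
## construction from long tables, duplicate-accession merging,
## organ-source ranking, Levenshtein profiles and hierarchical
## clustering of targets by their adverse-effect profiles.

.canon_term <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

.union_ci <- function(...) {
  x <- c(...)
  x <- x[!is.na(x) & nzchar(trimws(x))]
  x[!duplicated(.canon_term(x))]
}

#' Build an annotation set
#'
#' @param df long-format data.frame with columns `target_id`,
#'   `accession`, `organ_group`, `ae_term` and optionally `source_study`
#'   and `sequence_ref`. One row per (target, organ, term); a term may
#'   appear under several organ groups.
#' @return an `annotation_set`: list of per-target records (`target_id`,
#'   `accession`, `sequence_ref`, `ae_terms`, `organ_terms`,
#'   `source_study`).
#' @export
annotation_set <- function(df) {
  need <- c("target_id", "accession", "organ_group", "ae_term")
  stopifnot(all(need %in% names(df)))
  if (!"source_study" %in% names(df)) df$source_study <- NA_character_
  if (!"sequence_ref" %in% names(df)) df$sequence_ref <- NA_character_
  records <- lapply(split(df, df$accession), function(g) {
    organ_terms <- lapply(split(g$ae_term, g$organ_group), .union_ci)
    ae_terms <- .union_ci(g$ae_term)
    if (length(ae_terms) == 0L) {
      stop("target ", g$target_id[1], " has no adverse-effect terms")
    }
    seq_ref <- unique(g$sequence_ref[!is.na(g$sequence_ref)])
    if (length(seq_ref) > 1L) {
      stop("conflicting sequence references for accession ", g$accession[1])
    }
    list(target_id = g$target_id[1], accession = g$accession[1],
         sequence_ref = if (length(seq_ref)) seq_ref else NA_character_,
         ae_terms = ae_terms, organ_terms = organ_terms,
         source_study = unique(g$source_study[!is.na(g$source_study)]))
  })
  names(records) <- vapply(records, `[[`, character(1), "accession")
  structure(list(records = records), class = "annotation_set")
}

#' @export
length.annotation_set <- function(x) length(x$records)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d targets, %d adverse-effect terms\n",
              length(x$records),
              length(unique(unlist(lapply(x$records, function(r)
                .canon_term(r$ae_terms)))))))
  invisible(x)
}

#' Flatten an annotation set back to long format
#' @param x an `annotation_set`.
#' @param ... unused.
#' @export
as.data.frame.annotation_set <- function(x, ...) {
  rows <- lapply(x$records, function(r) {
    organ <- rep(names(r$organ_terms), lengths(r$organ_terms))
    term <- unlist(r$organ_terms, use.names = FALSE)
    extra <- setdiff(.canon_term(r$ae_terms), .canon_term(term))
    if (length(extra)) {
      keep <- r$ae_terms[.canon_term(r$ae_terms) %in% extra]
      organ <- c(organ, rep(NA_character_, length(keep)))
      term <- c(term, keep)
    }
    data.frame(target_id = r$target_id, accession = r$accession,
               organ_group = organ, ae_term = term,
               source_study = paste(r$source_study, collapse = "|"),
               sequence_ref = r$sequence_ref,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge two annotation sets
#'
#' Records sharing an accession are merged: adverse-effect terms are
#' unioned with case-insensitive deduplication, organ-group term lists
#' are unioned per group, and study sources are unioned. Conflicting
#' sequence references under one accession raise an error.
#'
#' @param a,b `annotation_set` objects.
#' @return the merged `annotation_set` (unique accessions).
#' @export
merge_annotation_sets <- function(a, b) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  records <- a$records
  for (acc in names(b$records)) {
    rb <- b$records[[acc]]
    if (!acc %in% names(records)) {
      records[[acc]] <- rb
      next
    }
    ra <- records[[acc]]
    if (!is.na(ra$sequence_ref) && !is.na(rb$sequence_ref) &&
        ra$sequence_ref != rb$sequence_ref) {
      stop("conflicting sequences under accession ", acc)
    }
    organs <- union(names(ra$organ_terms), names(rb$organ_terms))
    organ_terms <- stats::setNames(lapply(organs, function(o) {
      .union_ci(ra$organ_terms[[o]], rb$organ_terms[[o]])
    }), organs)
    records[[acc]] <- list(
      target_id = ra$target_id,
      accession = acc,
      sequence_ref = if (!is.na(ra$sequence_ref)) ra$sequence_ref else rb$sequence_ref,
      ae_terms = .union_ci(ra$ae_terms, rb$ae_terms),
      organ_terms = organ_terms,
      source_study = union(ra$source_study, rb$source_study)
    )
  }
  structure(list(records = records), class = "annotation_set")
}

#' Ranked organ string of a target
#'
#' Organ groups sorted by decreasing number of associated adverse-effect
#' terms, joined with "/"; ties broken alphabetically. In
#' "Lung/Heart/Kidney" the target has more lung-related terms than
#' heart, and more heart than kidney.
#'
#' @param record one record of an `annotation_set` (or an
#'   `annotation_set` and a `target` accession).
#' @return a single string.
#' @export
rank_organ_sources <- function(record) {
  if (inherits(record, "annotation_set")) {
    stop("pass a single record, e.g. set$records[[accession]]")
  }
  counts <- lengths(record$organ_terms)
  if (length(counts) == 0L) stop("record has no organ groups")
  ord <- order(-counts, names(counts))
  paste(names(counts)[ord], collapse = "/")
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(mapply(function(x, y) utils::adist(x, y), a, b))
}

#' Canonical adverse-effect profile string of a record
#'
#' Terms are lower-cased, whitespace-normalised, sorted and joined with
#' ";" so the profile is independent of term order and case.
#' @param record an annotation record.
#' @return a single string.
#' @export
ae_profile_string <- function(record) {
  paste(sort(unique(.canon_term(record$ae_terms))), collapse = ";")
}

#' Cluster targets by adverse-effect profile
#'
#' Computes pairwise Levenshtein distances between the canonicalised
#' adverse-effect profile strings of all targets, performs agglomerative
#' hierarchical clustering and cuts the dendrogram into exactly `k`
#' clusters.
#'
#' @param set an `annotation_set`.
#' @param k number of clusters (<= number of targets).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return named integer vector of cluster labels (names = target
#'   accessions), with the `hclust` tree attached as attribute `"tree"`.
#' @export
cluster_targets_by_ae <- function(set, k = 10L,
                                  linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(set, "annotation_set"))
  n <- length(set$records)
  if (k > n) stop("k = ", k, " exceeds the number of targets (", n, ")")
  profiles <- vapply(set$records, ae_profile_string, character(1))
  D <- utils::adist(profiles)
  dimnames(D) <- list(names(profiles), names(profiles))
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Export a clustering dendrogram as Newick
#' @param clustering result of [cluster_targets_by_ae()] (or an `hclust`).
#' @param path output file.
#' @export
write_cluster_newick <- function(clustering, path) {
  tree <- if (inherits(clustering, "hclust")) clustering else attr(clustering, "tree")
  if (is.null(tree)) stop("no dendrogram attached to this clustering")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Read / write annotation tables
#'
#' Long-format CSV/TSV with columns `target_id`, `accession`,
#' `organ_group`, `ae_term` (plus optional `source_study`,
#' `sequence_ref`), or a JSON round-trip format.
#'
#' @param path file path (.csv, .tsv or .json).
#' @return an `annotation_set`.
#' @export
read_annotation_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    return(annotation_set(df))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  annotation_set(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE,
                                   comment.char = "#", quote = "\""))
}

#' @rdname read_annotation_table
#' @param set an `annotation_set` to write.
#' @export
write_annotation_table <- function(set, path) {
  df <- as.data.frame(set)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Apply a declarative curation patch to an annotation set
#'
#' A patch is a list (or JSON file) of operations, each with fields
#' `action` ("add" or "remove"), `accession`, `organ_group` and
#' `ae_term`. Additions append the term to the organ group (creating the
#' group if needed); removals delete the term from the group.
#'
#' @param set an `annotation_set`.
#' @param patch list of operations, or path to a JSON patch file.
#' @return the patched `annotation_set`.
#' @export
apply_annotation_patch <- function(set, patch) {
  if (is.character(patch) && length(patch) == 1L) {
    patch <- jsonlite::fromJSON(patch, simplifyDataFrame = FALSE)
  }
  for (op in patch) {
    acc <- op$accession
    if (!acc %in% names(set$records)) {
      warning("patch references unknown accession ", acc, "; skipped")
      next
    }
    r <- set$records[[acc]]
    if (op$action == "add") {
      r$organ_terms[[op$organ_group]] <-
        .union_ci(r$organ_terms[[op$organ_group]], op$ae_term)
      r$ae_terms <- .union_ci(r$ae_terms, op$ae_term)
    } else if (op$action == "remove") {
      keep <- .canon_term(r$organ_terms[[op$organ_group]]) != .canon_term(op$ae_term)
      r$organ_terms[[op$organ_group]] <- r$organ_terms[[op$organ_group]][keep]
      still <- unlist(r$organ_terms, use.names = FALSE)
      r$ae_terms <- r$ae_terms[.canon_term(r$ae_terms) %in% .canon_term(still) |
                                 !.canon_term(r$ae_terms) %in% .canon_term(op$ae_term)]
    } else {
      stop("unknown patch action ", sQuote(op$action))
    }
    set$records[[acc]] <- r
  }
  set
}
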