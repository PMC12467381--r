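## Term-level evaluation: normalisation of free-text adverse-effect
## terms onto a preferred-term vocabulary (exact synonym lookup, then
## bounded edit-distance matching) and per-compound precision/recall of
## predicted versus ground-truth term sets.

#' Build a preferred-term dictionary
#'
#' @param preferred character vector of preferred terms.
#' @param synonyms optional data.frame with columns `synonym`,
#'   `preferred_term` mapping variants onto preferred terms; every
#'   preferred_term must be listed in `preferred`.
#' @return a `term_dictionary`.
#' @export
term_dictionary <- function(preferred, synonyms = NULL) {
  preferred <- .union_ci(preferred)
  lookup <- stats::setNames(preferred, .canon_term(preferred))
  if (!is.null(synonyms) && nrow(synonyms)) {
    stopifnot(all(c("synonym", "preferred_term") %in% names(synonyms)))
    bad <- setdiff(.canon_term(synonyms$preferred_term), .canon_term(preferred))
    if (length(bad)) {
      stop("synonyms map to unlisted preferred terms: ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
    pref_of <- stats::setNames(
      preferred[match(.canon_term(synonyms$preferred_term), .canon_term(preferred))],
      .canon_term(synonyms$synonym))
    # preferred terms win over synonym spellings on collision
    pref_of <- pref_of[!names(pref_of) %in% names(lookup)]
    lookup <- c(lookup, pref_of)
  }
  structure(list(preferred = preferred, lookup = lookup),
            class = "term_dictionary")
}

#' Read a term dictionary from CSV
#'
#' Two columns: `preferred_term`, `synonym` (one row per variant; rows
#' where both are equal just declare the preferred term). A real
#' preferred-term export in this shape loads directly.
#'
#' @param path CSV path.
#' @return a `term_dictionary`.
#' @export
read_term_dictionary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("preferred_term", "synonym") %in% names(df)))
  term_dictionary(unique(df$preferred_term),
                  df[df$synonym != df$preferred_term, , drop = FALSE])
}

#' @rdname read_term_dictionary
#' @param dict a `term_dictionary` to write.
#' @export
write_term_dictionary <- function(dict, path) {
  syn <- data.frame(preferred_term = unname(dict$lookup),
                    synonym = names(dict$lookup),
                    stringsAsFactors = FALSE)
  self_rows <- data.frame(preferred_term = dict$preferred,
                          synonym = .canon_term(dict$preferred),
                          stringsAsFactors = FALSE)
  out <- unique(rbind(self_rows, syn))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## text cleanup applied before any lookup: lower-case, trim, collapse
## whitespace, strip punctuation
.normalize_raw <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]", " ", x)
  gsub("\\s+", " ", trimws(x))
}

#' Normalise one term to a preferred term
#'
#' Pipeline: clean the raw string (case, whitespace, punctuation); exact
#' lookup against preferred terms and synonyms; otherwise the nearest
#' dictionary entry by Levenshtein distance, accepted when the distance
#' is at most `max_edit_fraction` of the longer string; otherwise
#' unmapped.
#'
#' @param raw free-text term.
#' @param dict a [term_dictionary()].
#' @param max_edit_fraction maximum accepted edit distance as a fraction
#'   of the longer string length (default 0.2).
#' @return list with `preferred` (string or NA) and `reason` (NA when
#'   mapped).
#' @export
normalize_term <- function(raw, dict, max_edit_fraction = 0.2) {
  stopifnot(inherits(dict, "term_dictionary"))
  if (length(dict$lookup) == 0L) stop("empty term dictionary")
  q <- .normalize_raw(raw)
  if (!nzchar(q)) return(list(preferred = NA_character_, reason = "empty"))
  hit <- dict$lookup[q]
  if (!is.na(hit)) return(list(preferred = unname(hit), reason = NA_character_))
  cand <- names(dict$lookup)
  d <- utils::adist(q, cand)[1, ]
  lim <- max_edit_fraction * pmax(nchar(q), nchar(cand))
  ok <- which(d <= lim)
  if (length(ok) == 0L) {
    return(list(preferred = NA_character_, reason = "no close match"))
  }
  # smallest distance wins; ties broken by preferred term alphabetically
  best <- ok[order(d[ok], unname(dict$lookup[ok]), cand[ok])][1]
  list(preferred = unname(dict$lookup[best]), reason = NA_character_)
}

#' Normalise a set of raw terms for one compound
#'
#' @param compound_id compound identifier.
#' @param terms character vector of raw terms.
#' @inheritParams normalize_term
#' @return a `normalized_term_set`: list with `compound_id`, `preferred`
#'   (unique preferred terms) and `unmapped` (data.frame raw/reason).
#' @export
normalize_term_set <- function(compound_id, terms, dict, max_edit_fraction = 0.2) {
  mapped <- character(0)
  un_raw <- character(0); un_reason <- character(0)
  for (t in unique(terms)) {
    r <- normalize_term(t, dict, max_edit_fraction)
    if (is.na(r$preferred)) {
      un_raw <- c(un_raw, t); un_reason <- c(un_reason, r$reason)
    } else {
      mapped <- c(mapped, r$preferred)
    }
  }
  structure(list(compound_id = compound_id,
                 preferred = sort(unique(mapped)),
                 unmapped = data.frame(raw = un_raw, reason = un_reason,
                                       stringsAsFactors = FALSE)),
            class = "normalized_term_set")
}

#' Predict raw adverse-effect terms from a screen
#'
#' A target counts as a predicted interactor when its interaction
#' distance is below the `threshold_quantile` quantile of the control
#' distances; the predicted term set is the union of the interactors'
#' adverse-effect terms. The rule and its quantile are recorded in the
#' output.
#'
#' @param compound_id compound identifier.
#' @param scores data.frame from [rank_targets()] restricted to
#'   annotated targets (`target_id`, `distance`).
#' @param annotations an `annotation_set`.
#' @param control_scores distances of the same compound to the control
#'   proteins in the same projection run.
#' @param threshold_quantile quantile of the control distances used as
#'   interaction threshold (default 0.05).
#' @return list with `compound_id`, `terms` (raw, pre-normalisation),
#'   `interactors` and `threshold`.
#' @export
predict_adverse_effect_terms <- function(compound_id, scores, annotations,
                                         control_scores,
                                         threshold_quantile = 0.05) {
  if (length(control_scores) == 0L) stop("empty control score set")
  thr <- stats::quantile(control_scores, threshold_quantile, names = FALSE)
  interactors <- scores$target_id[scores$distance < thr]
  terms <- unique(unlist(lapply(interactors, function(t) {
    r <- annotations$records[[t]]
    if (is.null(r)) character(0) else r$ae_terms
  })))
  list(compound_id = compound_id, terms = terms %||% character(0),
       interactors = interactors, threshold = thr,
       threshold_quantile = threshold_quantile)
}

#' Precision and recall of predicted versus ground-truth term sets
#'
#' True positives are the set intersection of preferred terms. Undefined
#' ratios (empty prediction or empty truth) are reported as NA, not 0,
#' so averages stay honest.
#'
#' @param predicted,truth `normalized_term_set` objects for the same
#'   compound (normalised against the same dictionary).
#' @return an `evaluation_result`: list with `compound_id`, `precision`,
#'   `recall` and the `tp`/`fp`/`fn` term vectors.
#' @export
precision_recall <- function(predicted, truth) {
  p <- unique(predicted$preferred)
  g <- unique(truth$preferred)
  tp <- intersect(p, g)
  fp <- setdiff(p, g)
  fn <- setdiff(g, p)
  structure(list(
    compound_id = predicted$compound_id,
    precision = if (length(p)) length(tp) / length(p) else NA_real_,
    recall = if (length(g)) length(tp) / length(g) else NA_real_,
    tp = sort(tp), fp = sort(fp), fn = sort(fn)
  ), class = "evaluation_result")
}

#' Read ground-truth adverse-effect lists
#'
#' CSV with columns `compound_id`, `ae_term` (one row per term);
#' per-drug dumps from side-effect resources load through this shape.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("compound_id", "ae_term") %in% names(df)))
  df
}
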