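## Self-contained synthetic screening world with planted interaction
## structure: compounds from a small guaranteed-parseable SMILES grammar
## (a subset containing a planted fragment), random protein sequences (a
## subset containing a planted motif), positive pairs defined by the
## motif rule, composition-matched decoys, adverse-effect annotations,
## and ground-truth term lists with injected spelling variants.

#' Fixed adverse-effect term vocabulary
#'
#' A small openly composed vocabulary of adverse-event terms, including
#' terms with British spellings whose American variants appear in the
#' synonym table of [synthetic_dictionary()].
#'
#' @return character vector of preferred terms.
#' @export
ae_term_vocabulary <- function() {
  c("nausea", "headache", "dizziness", "haemorrhage", "anaemia", "oedema",
    "diarrhoea", "vomiting", "constipation", "fatigue", "insomnia",
    "pruritus", "rash", "urticaria", "alopecia", "hypotension",
    "hypertension", "bradycardia", "tachycardia", "palpitations",
    "arrhythmia", "angina pectoris", "myocardial infarction",
    "heart failure", "dyspnoea", "cough", "bronchospasm", "pneumonitis",
    "pulmonary fibrosis", "renal failure", "proteinuria", "haematuria",
    "nephritis", "hepatotoxicity", "jaundice", "thrombocytopenia",
    "neutropenia", "leukopenia", "epistaxis", "ecchymosis",
    "gastrointestinal bleeding", "intracranial haemorrhage",
    "drowsiness", "tremor", "convulsions", "paraesthesia", "confusion",
    "depression")
}

# British -> American spelling swaps used for synonyms and variants
.spelling_swaps <- c(
  haemorrhage = "hemorrhage", anaemia = "anemia", oedema = "edema",
  diarrhoea = "diarrhea", dyspnoea = "dyspnea", haematuria = "hematuria",
  paraesthesia = "paresthesia", leukopenia = "leucopenia"
)

.organ_groups <- c("Heart", "Lung", "Kidney", "Cerebral", "Liver",
                   "Skin", "Other")

#' Term dictionary for the synthetic vocabulary
#'
#' Preferred terms are the vocabulary of [ae_term_vocabulary()];
#' synonyms cover British/American spelling swaps (applied to any word
#' of a multi-word term) and naive pluralisation. Random misspellings
#' injected by [generate_world()] are deliberately absent so that they
#' exercise the edit-distance stage of [normalize_term()].
#'
#' @return a [term_dictionary()].
#' @export
synthetic_dictionary <- function() {
  vocab <- ae_term_vocabulary()
  syn <- list()
  for (v in vocab) {
    sw <- .swap_spelling(v)
    if (!identical(sw, v)) syn[[length(syn) + 1L]] <- c(sw, v)
    syn[[length(syn) + 1L]] <- c(paste0(v, "s"), v)
  }
  syn_df <- data.frame(synonym = vapply(syn, `[`, "", 1L),
                       preferred_term = vapply(syn, `[`, "", 2L),
                       stringsAsFactors = FALSE)
  term_dictionary(vocab, syn_df)
}

.swap_spelling <- function(term) {
  words <- strsplit(term, " ")[[1]]
  hit <- words %in% names(.spelling_swaps)
  words[hit] <- .spelling_swaps[words[hit]]
  paste(words, collapse = " ")
}

.random_chain <- function(len) {
  paste(sample(c("C", "C", "C", "C", "N", "O"), len, replace = TRUE),
        collapse = "")
}

## one random scaffold SMILES: chain with optional branch, carbonyl
## decoration and small carbon ring
.random_scaffold <- function() {
  len <- sample(5:11, 1)
  s <- .random_chain(len)
  if (stats::runif(1) < 0.35) {
    at <- sample(seq_len(nchar(s) - 1), 1)
    s <- paste0(substr(s, 1, at), "(", sample(c("C", "O", "C(=O)C"), 1), ")",
                substr(s, at + 1, nchar(s)))
  }
  if (stats::runif(1) < 0.25) {
    ring <- paste0("C1", strrep("C", sample(2:4, 1)), "C1")
    s <- paste0(s, ring)
  }
  s
}

## insert a fragment into a scaffold chain at a random position between
## two backbone atoms
.insert_fragment <- function(scaffold, fragment) {
  bb <- gregexpr("[CNO](?![0-9)])", scaffold, perl = TRUE)[[1]]
  cand <- bb[bb > 1]
  cut <- if (length(cand) == 1L) cand else sample(cand, 1)
  paste0(substr(scaffold, 1, cut - 1), fragment,
         substr(scaffold, cut, nchar(scaffold)))
}

.random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

.insert_motif <- function(seq, motif) {
  at <- sample(seq_len(nchar(seq) - nchar(motif) + 1L), 1)
  paste0(substr(seq, 1, at - 1), motif,
         substr(seq, at + nchar(motif), nchar(seq)))
}

## single-character misspelling (substitute/insert/delete), never the
## identity
.misspell <- function(term) {
  letters_pool <- letters
  repeat {
    op <- sample(c("sub", "ins", "del"), 1)
    i <- sample(nchar(term), 1)
    out <- switch(op,
      sub = paste0(substr(term, 1, i - 1), sample(letters_pool, 1),
                   substr(term, i + 1, nchar(term))),
      ins = paste0(substr(term, 1, i), sample(letters_pool, 1),
                   substr(term, i + 1, nchar(term))),
      del = paste0(substr(term, 1, i - 1), substr(term, i + 1, nchar(term)))
    )
    if (out != term && nchar(out) > 0) return(out)
  }
}

.variant_of <- function(term) {
  sw <- .swap_spelling(term)
  if (sw != term) return(sw)
  if (nchar(term) >= 8 && stats::runif(1) < 0.5) return(.misspell(term))
  paste0(term, "s")
}

#' Generate a synthetic screening world
#'
#' Builds a deterministic (seeded) world in which interaction is
#' governed by a planted rule: a compound interacts with a target if and
#' only if the compound's structure contains a planted fragment and the
#' target's sequence contains a planted motif. Positive pairs all
#' satisfy the rule; sampled negatives and decoys all violate it. Decoy
#' compounds carry a composition-matched but topologically different
#' variant of the fragment (carbonyls replaced by hydroxyls), mimicking
#' property-matched decoy sets at toy scale.
#'
#' @param n_compounds number of compounds (default 200).
#' @param n_targets number of adverse-effect-annotated, motif-bearing
#'   targets (default 100).
#' @param n_controls number of motif-free control proteins (default
#'   `n_targets`).
#' @param n_positive_per_target active compounds paired with each target
#'   (default 2).
#' @param motif_smiles_fragment planted SMILES fragment, insertable into
#'   a chain (default an imide-like `"C(=O)NC(=O)"`).
#' @param motif_sequence planted amino-acid motif.
#' @param ae_vocab_size number of vocabulary terms actually used.
#' @param variant_rate fraction of ground-truth terms replaced by
#'   spelling/synonym variants (in `[0, 1]`).
#' @param frac_active fraction of compounds carrying the fragment.
#' @param planted if FALSE, build the null world: identical entities but
#'   pair labels assigned at random, irrespective of the motif rule.
#' @param seed integer seed; identical seeds give identical worlds.
#' @return a `synthetic_world` list; see Details.
#' @details The returned list has elements `compounds` (data.frame with
#'   `compound_id`, `smiles`, `is_active`), `proteins` (`protein_id`,
#'   `sequence`, `kind`), `pairs` (labelled interaction table),
#'   `positives`, `decoy_pool`, `annotations` (an `annotation_set`),
#'   `ground_truth` (`compound_id`, `ae_term`), `dictionary` and
#'   `params`.
#' @export
generate_world <- function(n_compounds = 200L, n_targets = 100L,
                           n_controls = n_targets,
                           n_positive_per_target = 2L,
                           motif_smiles_fragment = "C(=O)NC(=O)",
                           motif_sequence = "WHMKFWHMKFWH",
                           ae_vocab_size = 40L, variant_rate = 0.1,
                           frac_active = 0.4, planted = TRUE, seed = 7L) {
  stopifnot(n_compounds >= 4L, n_targets >= 1L, n_controls >= 0L,
            n_positive_per_target >= 1L,
            variant_rate >= 0, variant_rate <= 1)
  # the fragment must be chemically embeddable in a chain
  ok <- tryCatch({
    parse_smiles(paste0("C", motif_smiles_fragment, "C"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("motif fragment ", sQuote(motif_smiles_fragment),
                " is not embeddable in a chain")
  decoy_fragment <- gsub("(=O)", "(O)", motif_smiles_fragment, fixed = TRUE)

  withr::with_seed(seed, {
    ## compounds -----------------------------------------------------
    n_active <- max(2L, round(n_compounds * frac_active))
    n_decoy <- (n_compounds - n_active) %/% 2L
    n_plain <- n_compounds - n_active - n_decoy
    gen_until_clean <- function(build) {
      for (i in 1:50) {
        s <- build()
        if (!grepl(motif_smiles_fragment, s, fixed = TRUE)) return(s)
      }
      stop("could not generate a fragment-free scaffold")
    }
    smiles <- c(
      vapply(seq_len(n_active), function(i)
        .insert_fragment(.random_scaffold(), motif_smiles_fragment),
        character(1)),
      vapply(seq_len(n_decoy), function(i)
        gen_until_clean(function()
          .insert_fragment(.random_scaffold(), decoy_fragment)),
        character(1)),
      vapply(seq_len(n_plain), function(i)
        gen_until_clean(.random_scaffold), character(1))
    )
    compounds <- data.frame(
      compound_id = sprintf("CMPD%04d", seq_len(n_compounds)),
      smiles = smiles,
      is_active = rep(c(TRUE, FALSE), c(n_active, n_compounds - n_active)),
      stringsAsFactors = FALSE
    )

    ## proteins ------------------------------------------------------
    target_ids <- sprintf("AET%03d", seq_len(n_targets))
    control_ids <- if (n_controls > 0) sprintf("CTRL%04d", seq_len(n_controls))
                   else character(0)
    target_seq <- vapply(seq_len(n_targets), function(i)
      .insert_motif(.random_protein(sample(80:140, 1)), motif_sequence),
      character(1))
    control_seq <- vapply(seq_len(n_controls), function(i) {
      repeat {
        s <- .random_protein(sample(80:140, 1))
        if (!grepl(motif_sequence, s, fixed = TRUE)) return(s)
      }
    }, character(1))
    proteins <- data.frame(
      protein_id = c(target_ids, control_ids),
      sequence = c(target_seq, control_seq),
      kind = rep(c("ae_target", "control_protein"), c(n_targets, n_controls)),
      stringsAsFactors = FALSE
    )

    ## interaction pairs ---------------------------------------------
    active_ids <- compounds$compound_id[compounds$is_active]
    positives <- do.call(rbind, lapply(target_ids, function(t) {
      data.frame(compound_id = sample(active_ids,
                                      min(n_positive_per_target,
                                          length(active_ids))),
                 target_id = t, stringsAsFactors = FALSE)
    }))
    n_pos <- nrow(positives)
    # negatives violate the motif rule: at least one side lacks its motif
    neg_keys <- character(0)
    negatives <- NULL
    non_active_ids <- compounds$compound_id[!compounds$is_active]
    while (is.null(negatives) || nrow(negatives) < n_pos) {
      m <- n_pos - if (is.null(negatives)) 0L else nrow(negatives)
      cand <- data.frame(
        compound_id = sample(compounds$compound_id, m, replace = TRUE),
        target_id = sample(c(target_ids, control_ids), m, replace = TRUE),
        stringsAsFactors = FALSE
      )
      rule <- cand$compound_id %in% active_ids & cand$target_id %in% target_ids
      cand <- cand[!rule, , drop = FALSE]
      key <- paste(cand$compound_id, cand$target_id)
      cand <- cand[!duplicated(key) & !key %in% neg_keys, , drop = FALSE]
      neg_keys <- c(neg_keys, paste(cand$compound_id, cand$target_id))
      negatives <- rbind(negatives, cand)
    }
    pairs <- rbind(
      cbind(positives, label = 1L),
      cbind(negatives, label = 0L)
    )
    rownames(pairs) <- NULL
    if (!planted) {
      pairs$label <- sample(pairs$label) # null world: labels shuffled
    }

    ## adverse-effect annotations ------------------------------------
    vocab <- utils::head(ae_term_vocabulary(), ae_vocab_size)
    ann_rows <- do.call(rbind, lapply(target_ids, function(t) {
      terms <- sample(vocab, sample(2:8, 1))
      organs <- sample(.organ_groups, sample(1:3, 1))
      data.frame(target_id = t, accession = t,
                 organ_group = sample(organs, length(terms), replace = TRUE),
                 ae_term = terms, source_study = "synthetic",
                 stringsAsFactors = FALSE)
    }))
    annotations <- annotation_set(ann_rows)

    ## ground-truth term lists with injected variants ----------------
    gt_rows <- list()
    for (cid in unique(positives$compound_id)) {
      tg <- positives$target_id[positives$compound_id == cid]
      terms <- unique(unlist(lapply(tg, function(t)
        annotations$records[[t]]$ae_terms)))
      n_var <- round(length(terms) * variant_rate)
      if (n_var > 0) {
        vi <- sample(length(terms), n_var)
        terms[vi] <- vapply(terms[vi], .variant_of, character(1))
      }
      gt_rows[[cid]] <- data.frame(compound_id = cid, ae_term = terms,
                                   stringsAsFactors = FALSE)
    }
    ground_truth <- do.call(rbind, gt_rows)
    rownames(ground_truth) <- NULL
  })

  structure(list(
    compounds = compounds, proteins = proteins, pairs = pairs,
    positives = positives,
    decoy_pool = compounds$compound_id[!compounds$is_active],
    annotations = annotations, ground_truth = ground_truth,
    dictionary = synthetic_dictionary(),
    params = list(n_compounds = as.integer(n_compounds),
                  n_targets = as.integer(n_targets),
                  n_controls = as.integer(n_controls),
                  n_positive_per_target = as.integer(n_positive_per_target),
                  motif_smiles_fragment = motif_smiles_fragment,
                  motif_sequence = motif_sequence,
                  ae_vocab_size = as.integer(ae_vocab_size),
                  variant_rate = variant_rate, frac_active = frac_active,
                  planted = planted, seed = as.integer(seed))
  ), class = "synthetic_world")
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits every file in the formats the other modules read: a FASTA of
#' all proteins, a compound table, a labelled pair table, a long-format
#' annotation table, the term dictionary and the ground-truth lists,
#' plus a JSON file of the generation parameters for lossless
#' regeneration.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
world_to_files <- function(world, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir)
  }
  paths <- c(
    proteins = file.path(dir, "proteins.fasta"),
    compounds = file.path(dir, "compounds.csv"),
    pairs = file.path(dir, "pairs.csv"),
    annotations = file.path(dir, "annotations.csv"),
    dictionary = file.path(dir, "dictionary.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    params = file.path(dir, "world.json")
  )
  tryCatch({
    write_protein_fasta(world$proteins, paths["proteins"])
    utils::write.csv(world$compounds, paths["compounds"], row.names = FALSE)
    utils::write.csv(world$pairs, paths["pairs"], row.names = FALSE)
    write_annotation_table(world$annotations, paths["annotations"])
    write_term_dictionary(world$dictionary, paths["dictionary"])
    utils::write.csv(world$ground_truth, paths["ground_truth"], row.names = FALSE)
    jsonlite::write_json(world$params, paths["params"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e) {
    stop("failed writing world files under ", dir, ": ", conditionMessage(e))
  })
  invisible(paths)
}

#' Rebuild a synthetic world from its written parameter file
#'
#' Reads `world.json` from a [world_to_files()] directory and re-runs
#' the seeded generator, giving a world equal to the original on all
#' fields.
#'
#' @param dir directory written by [world_to_files()].
#' @return a `synthetic_world`.
#' @export
world_from_files <- function(dir) {
  pth <- file.path(dir, "world.json")
  if (!file.exists(pth)) stop("no world.json under ", dir)
  p <- jsonlite::fromJSON(pth)
  generate_world(
    n_compounds = p$n_compounds, n_targets = p$n_targets,
    n_controls = p$n_controls,
    n_positive_per_target = p$n_positive_per_target,
    motif_smiles_fragment = p$motif_smiles_fragment,
    motif_sequence = p$motif_sequence, ae_vocab_size = p$ae_vocab_size,
    variant_rate = p$variant_rate, frac_active = p$frac_active,
    planted = p$planted, seed = p$seed
  )
}
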