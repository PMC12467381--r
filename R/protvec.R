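## Protein featurisation: sequences are split into overlapping k-mer
## "sentences" (one per shifted reading frame, the ProtVec convention),
## a skip-gram model is trained on those sentences, and a protein's
## embedding is the sum (optionally mean) of its k-mer vectors.

#' Split sequences into k-mer sentences
#'
#' Each sequence yields up to `frames` sentences; frame `f` (0-based
#' shift) contains the k-mers starting at positions f+1, f+1+frames,
#' f+1+2*frames, ... With `frames = k` (the classic convention) each
#' sentence holds non-overlapping k-mers and the frames jointly cover
#' every overlapping k-mer of the sequence; with `frames = 1` a single
#' sentence holds all overlapping k-mers. Sequences are upper-cased;
#' non-standard residue symbols are kept as literal characters.
#'
#' @param sequences character vector of amino-acid sequences.
#' @param k k-mer size (default 3).
#' @param frames number of shifted reading frames (default `k`).
#' @return list of character vectors (sentences of k-mer words).
#' @export
kmer_sentences <- function(sequences, k = 3L, frames = k) {
  stopifnot(k >= 1L, frames >= 1L)
  sequences <- toupper(sequences)
  out <- list()
  for (s in sequences) {
    n <- nchar(s)
    for (f in seq_len(frames) - 1L) {
      if (n - k + 1L < 1L + f) next
      starts <- seq.int(1L + f, n - k + 1L, by = frames)
      out[[length(out) + 1L]] <- substring(s, starts, starts + k - 1L)
    }
  }
  out
}

#' Train skip-gram embeddings over protein k-mers
#'
#' Trains word2vec-style skip-gram with negative sampling on the k-mer
#' sentences of a sequence corpus. Training is bit-reproducible under a
#' fixed seed (internal deterministic RNG, fixed sentence order).
#'
#' @param sequences amino-acid sequence corpus (character vector).
#' @param k k-mer size. @param dimension embedding dimension.
#' @param window context window half-width.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param frames reading frames per sequence (default `k`).
#' @param negative negative samples per positive pair.
#' @param lr initial learning rate (linearly decayed to `lr/10`).
#' @return a `kmer_embedding_table`: list with `k`, `dimension`,
#'   `vectors` (matrix, one row per k-mer, row names = k-mers) and
#'   training metadata.
#' @export
train_kmer_embeddings <- function(sequences, k = 3L, dimension = 100L,
                                  window = 5L, epochs = 5L, seed = 1L,
                                  frames = k, negative = 5L, lr = 0.025) {
  sequences <- sequences[!is.na(sequences)]
  if (length(sequences) == 0L || all(nchar(sequences) < k)) {
    stop("empty k-mer corpus: need at least one sequence of length >= k")
  }
  sents <- kmer_sentences(sequences, k = k, frames = frames)
  vocab <- sort(unique(unlist(sents)))
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  sents_i <- lapply(sents, function(s) unname(idx[s]))
  counts <- tabulate(unlist(sents_i) + 1L, nbins = length(vocab))
  vec <- .sgns_train(sents_i, as.integer(counts), as.integer(dimension),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), lr, lr / 10, as.integer(seed))
  rownames(vec) <- vocab
  structure(
    list(k = as.integer(k), dimension = as.integer(dimension), vectors = vec,
         meta = list(window = as.integer(window), epochs = as.integer(epochs),
                     seed = as.integer(seed), negative = as.integer(negative),
                     frames = as.integer(frames), lr = lr)),
    class = "kmer_embedding_table"
  )
}

#' Embed a protein sequence with a k-mer embedding table
#'
#' Sums the embedding vectors of all k-mers drawn from `frames` shifted
#' reading frames of the sequence. K-mers absent from the table
#' contribute the zero vector. `aggregate = "mean"` divides by the number
#' of k-mers instead.
#'
#' @param sequence amino-acid string (length >= k).
#' @param table a [train_kmer_embeddings()] table (or one loaded with
#'   [read_kmer_table()]).
#' @param frames number of reading frames (default from the table).
#' @param aggregate `"sum"` (default, original convention) or `"mean"`.
#' @return numeric vector of length `table$dimension`.
#' @export
protein_embed <- function(sequence, table, frames = NULL, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(table, "kmer_embedding_table"))
  frames <- frames %||% table$meta$frames %||% table$k
  k <- table$k
  if (is.na(sequence) || nchar(sequence) < k) {
    stop("sequence shorter than k = ", k, "; cannot embed")
  }
  kmers <- unlist(kmer_sentences(sequence, k = k, frames = frames))
  hit <- kmers[kmers %in% rownames(table$vectors)]
  if (length(hit) == 0L) return(numeric(table$dimension))
  v <- colSums(table$vectors[hit, , drop = FALSE])
  if (aggregate == "mean") v <- v / length(kmers)
  unname(v)
}

#' Build protein records with embeddings
#'
#' @param protein_id,sequence parallel character vectors.
#' @param table k-mer embedding table.
#' @inheritParams protein_embed
#' @return a `protein_set`: list with `ids`, `sequences` and embedding
#'   matrix `features` (proteins in rows).
#' @export
protein_records <- function(protein_id, sequence, table, frames = NULL,
                            aggregate = "sum") {
  stopifnot(length(protein_id) == length(sequence))
  if (anyDuplicated(protein_id)) stop("duplicate protein ids")
  feats <- matrix(0, length(sequence), table$dimension,
                  dimnames = list(protein_id, NULL))
  for (i in seq_along(sequence)) {
    feats[i, ] <- protein_embed(sequence[i], table, frames = frames,
                                aggregate = aggregate)
  }
  if (any(!is.finite(feats))) stop("non-finite protein embedding")
  structure(
    list(ids = protein_id,
         sequences = stats::setNames(toupper(sequence), protein_id),
         features = feats, dimension = table$dimension),
    class = "protein_set"
  )
}

#' Pair up the two modality embeddings for the interaction model
#'
#' Slot 1 is always the target (protein) embedding and slot 2 the
#' compound fingerprint, matching the model's modality index convention.
#'
#' @param compound a row of a `compound_set` (use `compound_id`).
#' @param protein a row of a `protein_set` (use `protein_id`).
#' @param compounds,proteins the feature stores.
#' @param compound_id,protein_id entity identifiers.
#' @return list with `E1` (target embedding) and `E2` (compound
#'   fingerprint).
#' @export
featurize_pair <- function(compounds, proteins, compound_id, protein_id) {
  if (!compound_id %in% compounds$ids) {
    stop("no features for compound ", sQuote(compound_id))
  }
  if (!protein_id %in% proteins$ids) {
    stop("no features for protein ", sQuote(protein_id))
  }
  list(E1 = unname(proteins$features[protein_id, ]),
       E2 = unname(compounds$features[compound_id, ]))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file. Record id = first whitespace-delimited token
#'   of the header line.
#' @return data.frame with columns `protein_id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  data.frame(protein_id = ids, sequence = as.character(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#' @param df data.frame with `protein_id`, `sequence`.
#' @param path output path.
#' @export
write_protein_fasta <- function(df, path) {
  x <- Biostrings::AAStringSet(stats::setNames(df$sequence, df$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a k-mer embedding table in plain-text word2vec format
#'
#' First line: "<count> <dim>"; then one k-mer and its vector per line.
#' @param table a `kmer_embedding_table`.
#' @param path output path.
#' @export
write_kmer_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$dimension), con)
  apply_fmt <- apply(table$vectors, 1, function(v)
    paste(sprintf("%.8g", v), collapse = " "))
  writeLines(paste(rownames(table$vectors), apply_fmt), con)
  invisible(path)
}

#' Read a plain-text word2vec k-mer table
#' @param path file written by [write_kmer_table()] (or any word2vec
#'   text-format export).
#' @param k k-mer size; defaults to the word length found in the file.
#' @return a `kmer_embedding_table`.
#' @export
read_kmer_table <- function(path, k = NULL) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  words <- vapply(body, `[`, character(1), 1L)
  vec <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(hdr[2])))
  rownames(vec) <- words
  structure(
    list(k = as.integer(k %||% nchar(words[1])), dimension = hdr[2],
         vectors = vec, meta = list(frames = as.integer(k %||% nchar(words[1])))),
    class = "kmer_embedding_table"
  )
}
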