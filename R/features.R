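# Composition feature extraction.
#
# Twelve feature models combine up to six blocks: amino-acid 2-mer and 3-mer
# frequencies (400 and 8,000 features), side-chain-alphabet 2/3/4-mer
# frequencies (49, 343 and 2,401 features) and eight physicochemical "extra"
# descriptors. k-mer windows overlap; frequencies are counts divided by the
# number of valid windows, so every k-mer block of a sequence of length >= k
# sums to exactly 1. Windows containing the unknown residue X are excluded
# from both numerator and denominator.

# cache of k-mer name vectors, keyed by alphabet string + k
.kmer_name_cache <- new.env(parent = emptyenv())

kmer_names <- function(letters_set, k) {
  key <- paste0(paste(letters_set, collapse = ""), "_", k)
  if (!is.null(.kmer_name_cache[[key]])) return(.kmer_name_cache[[key]])
  grid <- do.call(expand.grid,
                  c(rep(list(letters_set), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  nm <- do.call(paste0, grid[, k:1, drop = FALSE])
  .kmer_name_cache[[key]] <- nm
  nm
}

encode_letters <- function(sequence, letters_set) {
  match(strsplit(sequence, "")[[1]], letters_set)
}

#' Translate an amino-acid sequence into the side-chain alphabet
#'
#' Replaces each residue by its 7-group side-chain symbol. The unknown
#' residue X passes through unchanged (it is later excluded from k-mer
#' windows); any other unmapped letter is an error naming its position.
#'
#' @param sequence Amino-acid string (sanitized, see [read_fasta()]).
#' @param alphabet A [side_chain_alphabet()].
#' @return Group-symbol string of the same length as `sequence`.
#' @examples
#' translate_side_chain("KRH")  # one group: basic
#' @export
translate_side_chain <- function(sequence, alphabet = side_chain_alphabet()) {
  letters <- strsplit(sequence, "")[[1]]
  out <- unname(alphabet$groups[letters])
  out[letters == "X"] <- "X"
  if (anyNA(out)) {
    pos <- which(is.na(out))[1]
    stop("unmapped letter '", letters[pos], "' at position ", pos)
  }
  paste(out, collapse = "")
}

#' Overlapping k-mer frequencies of a protein sequence
#'
#' Counts all `nchar(sequence) - k + 1` overlapping windows and divides by
#' the number of valid windows. Windows containing X are dropped from both
#' counts and the denominator. The returned vector is ordered
#' lexicographically over the alphabet (the canonical feature order).
#'
#' @param sequence Amino-acid string, or a side-chain-translated string when
#'   `alphabet` is a [side_chain_alphabet()].
#' @param k Window size, one of 2, 3 or 4.
#' @param alphabet `"aa"` for the 20-letter canonical alphabet (default) or a
#'   [side_chain_alphabet()]; in the latter case the sequence is translated
#'   first (passing an already-translated string gives the same result).
#' @return Named numeric vector of length `A^k` summing to 1 for sequences
#'   with at least one valid window; all-zero (with a warning) for sequences
#'   shorter than `k`.
#' @examples
#' kmer_frequencies("ACDA", 2)[c("AC", "CD", "DA")]
#' @export
kmer_frequencies <- function(sequence, k, alphabet = "aa") {
  stopifnot(k %in% 2:4)
  if (inherits(alphabet, "side_chain_alphabet")) {
    letters_set <- alphabet$symbols
    if (grepl(paste0("[", paste(AA_LETTERS, collapse = ""), "]"), sequence)) {
      sequence <- translate_side_chain(sequence, alphabet)
    }
  } else if (identical(alphabet, "aa")) {
    letters_set <- AA_LETTERS
  } else {
    stop("alphabet must be \"aa\" or a side_chain_alphabet object")
  }
  A <- length(letters_set)
  nm <- kmer_names(letters_set, k)
  codes <- encode_letters(sequence, letters_set)
  n <- length(codes)
  if (n < k) {
    warning("sequence shorter than k = ", k, "; returning all-zero vector")
    return(stats::setNames(numeric(A^k), nm))
  }
  v <- codes[1:(n - k + 1)] - 1L
  for (j in 2:k) v <- v * A + (codes[j:(n - k + j)] - 1L)
  valid <- !is.na(v)
  counts <- tabulate(v[valid] + 1L, nbins = A^k)
  n_valid <- sum(valid)
  if (n_valid == 0) {
    warning("no valid k-mer windows (all contain X); returning all-zero vector")
    return(stats::setNames(numeric(A^k), nm))
  }
  stats::setNames(counts / n_valid, nm)
}

EXTRA_FEATURE_NAMES <- c("isoelectric_point", "instability_index", "length",
                         "aromaticity", "extinction_reduced",
                         "extinction_cystines", "gravy", "molecular_weight")

net_charge_at_ph <- function(pH, n_pos, n_neg) {
  pos <- sum(n_pos / (1 + 10^(pH - PKA_POSITIVE[names(n_pos)])))
  neg <- sum(n_neg / (1 + 10^(PKA_NEGATIVE[names(n_neg)] - pH)))
  pos - neg
}

#' Physicochemical descriptors of a protein sequence
#'
#' Computes the eight "extra" features: isoelectric point (bisection on the
#' Henderson-Hasselbalch net charge, EMBOSS pKa set, tolerance 0.001 pH),
#' Guruprasad instability index, sequence length, aromaticity (fraction of
#' F/W/Y), molar extinction coefficients at 280 nm assuming all cysteines
#' reduced and assuming `floor(nC/2)` cystine bridges, GRAVY (mean
#' Kyte-Doolittle hydropathy) and average molecular weight. X residues count
#' toward length but are excluded from every chemical sum.
#'
#' @param sequence Sanitized amino-acid string, length >= 1.
#' @return Named numeric vector of length 8 in the documented order
#'   (`isoelectric_point`, `instability_index`, `length`, `aromaticity`,
#'   `extinction_reduced`, `extinction_cystines`, `gravy`,
#'   `molecular_weight`).
#' @examples
#' compute_extra_features("FWY")[["aromaticity"]]  # 1
#' @export
compute_extra_features <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  L <- length(letters)
  if (L == 0) stop("cannot compute features of an empty sequence")
  canon <- letters[letters %in% AA_LETTERS]
  counts <- table(factor(canon, levels = AA_LETTERS))
  cn <- as.numeric(counts); names(cn) <- AA_LETTERS

  aromaticity <- sum(cn[c("F", "W", "Y")]) / L
  gravy <- if (length(canon) > 0) mean(KD_HYDROPATHY[canon]) else 0
  mw <- sum(cn * (AA_MASS_FREE - WATER_MASS)) + WATER_MASS
  ext_red <- EXT_TRP * cn[["W"]] + EXT_TYR * cn[["Y"]]
  ext_cys <- ext_red + EXT_CYSTINE * floor(cn[["C"]] / 2)

  # instability: 10/L times the sum of dipeptide weights, X-containing
  # dipeptides skipped
  ii <- 0
  if (L >= 2) {
    a <- letters[-L]; b <- letters[-1]
    ok <- a %in% AA_LETTERS & b %in% AA_LETTERS
    if (any(ok)) ii <- (10 / L) * sum(DIWV[cbind(a[ok], b[ok])])
  }

  n_pos <- c(Nterm = 1, K = cn[["K"]], R = cn[["R"]], H = cn[["H"]])
  n_neg <- c(Cterm = 1, D = cn[["D"]], E = cn[["E"]], C = cn[["C"]],
             Y = cn[["Y"]])
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(mid, n_pos, n_neg) > 0) lo <- mid else hi <- mid
  }
  pi_val <- (lo + hi) / 2

  stats::setNames(
    c(pi_val, ii, L, aromaticity, ext_red, ext_cys, gravy, mw),
    EXTRA_FEATURE_NAMES
  )
}

MODEL_NAMES <- c("di_sc", "di_sc_p", "tri_sc", "tri_sc_p", "tetra_sc",
                 "tetra_sc_p", "di", "di_p", "tri", "tri_p",
                 "tetra_sc_tri_p", "all")

MODEL_BLOCKS <- list(
  di_sc          = "sc-2mer",
  di_sc_p        = c("sc-2mer", "extra"),
  tri_sc         = "sc-3mer",
  tri_sc_p       = c("sc-3mer", "extra"),
  tetra_sc       = "sc-4mer",
  tetra_sc_p     = c("sc-4mer", "extra"),
  di             = "aa-2mer",
  di_p           = c("aa-2mer", "extra"),
  tri            = "aa-3mer",
  tri_p          = c("aa-3mer", "extra"),
  tetra_sc_tri_p = c("aa-3mer", "sc-4mer", "extra"),
  all            = c("aa-2mer", "aa-3mer", "sc-2mer", "sc-3mer", "sc-4mer",
                     "extra")
)

block_feature_names <- function(kind, sc_alphabet) {
  switch(kind,
    "aa-2mer" = paste0("aa2_", kmer_names(AA_LETTERS, 2)),
    "aa-3mer" = paste0("aa3_", kmer_names(AA_LETTERS, 3)),
    "sc-2mer" = paste0("sc2_", kmer_names(sc_alphabet$symbols, 2)),
    "sc-3mer" = paste0("sc3_", kmer_names(sc_alphabet$symbols, 3)),
    "sc-4mer" = paste0("sc4_", kmer_names(sc_alphabet$symbols, 4)),
    "extra"   = EXTRA_FEATURE_NAMES,
    stop("unknown block kind: ", kind)
  )
}

#' Available feature-model names
#' @return Character vector of the 12 model names.
#' @export
model_names <- function() MODEL_NAMES

#' Build the feature schema of one model
#'
#' A schema is the ordered list of feature blocks of one of the 12 models,
#' with the full feature-name vector and total dimension. Block widths are
#' fixed: amino-acid 2-mers 400, 3-mers 8,000; side-chain 2-mers 49, 3-mers
#' 343, 4-mers 2,401; extras 8. The widest model, `"all"`, has 11,201
#' features; the production model `"tetra_sc_tri_p"` has 10,409.
#'
#' @param model_name One of [model_names()].
#' @param sc_alphabet Side-chain alphabet used by `sc-*` blocks.
#' @return Object of class `feature_schema`: list with `model_name`, `blocks`
#'   (tibble of `kind`, `dim`), `feature_names`, `total_dim`, `sc_alphabet`.
#' @examples
#' feature_schema("all")$total_dim       # 11201
#' feature_schema("tetra_sc_tri_p")$total_dim  # 10409
#' @export
feature_schema <- function(model_name, sc_alphabet = side_chain_alphabet()) {
  if (!model_name %in% MODEL_NAMES) {
    stop("unknown model '", model_name, "'; valid models: ",
         paste(MODEL_NAMES, collapse = ", "))
  }
  kinds <- MODEL_BLOCKS[[model_name]]
  names_by_block <- lapply(kinds, block_feature_names, sc_alphabet = sc_alphabet)
  blocks <- tibble::tibble(kind = kinds, dim = lengths(names_by_block))
  structure(
    list(model_name = model_name, blocks = blocks,
         feature_names = unlist(names_by_block, use.names = FALSE),
         total_dim = sum(blocks$dim), sc_alphabet = sc_alphabet),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> model:", x$model_name, "-", x$total_dim, "features\n")
  for (i in seq_len(nrow(x$blocks))) {
    cat("  ", format(x$blocks$kind[i], width = 8), x$blocks$dim[i], "\n")
  }
  invisible(x)
}

extract_one <- function(sequence, schema) {
  sc_seq <- NULL
  vals <- lapply(schema$blocks$kind, function(kind) {
    if (kind == "extra") return(compute_extra_features(sequence))
    if (startsWith(kind, "sc")) {
      if (is.null(sc_seq)) {
        sc_seq <<- translate_side_chain(sequence, schema$sc_alphabet)
      }
      k <- as.integer(substr(kind, 4, 4))
      kmer_frequencies(sc_seq, k, schema$sc_alphabet)
    } else {
      k <- as.integer(substr(kind, 4, 4))
      kmer_frequencies(sequence, k, "aa")
    }
  })
  unlist(vals, use.names = FALSE)
}

#' Extract a feature matrix from protein records
#'
#' Applies every block extractor of a schema to each record and binds the
#' results row-wise. Extra features are returned raw; standardization is a
#' training-time concern handled per fold by the ensemble (see
#' [train_fold()]).
#'
#' @param records Record tibble (columns `id`, `sequence`).
#' @param schema A [feature_schema()], or a model name.
#' @return Numeric matrix, one row per record (rownames = ids), columns in
#'   schema order with the schema attached as attribute `"schema"`.
#' @examples
#' recs <- tibble::tibble(id = "p1", sequence = "MKVLAE")
#' dim(extract_features(recs, "di"))
#' @export
extract_features <- function(records, schema) {
  if (is.character(schema)) schema <- feature_schema(schema)
  stopifnot(inherits(schema, "feature_schema"))
  m <- matrix(0, nrow = nrow(records), ncol = schema$total_dim,
              dimnames = list(records$id, schema$feature_names))
  for (i in seq_len(nrow(records))) {
    m[i, ] <- extract_one(records$sequence[[i]], schema)
  }
  attr(m, "schema") <- schema
  m
}
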