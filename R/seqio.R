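# FASTA I/O and class labelling.
#
# Protein records are plain tibbles with columns id, description, sequence
# and (optionally) label, so they pipe straight into dplyr verbs. Reading
# and writing go through Biostrings.

#' Default virion structural class list
#'
#' The ten phage structural protein classes plus the background class
#' "others", in a fixed documented order. The order is load-bearing: it
#' defines network output order and the deterministic tie-break in
#' [classify_scores()].
#'
#' @param include_others Keep the background class? Default `TRUE`.
#' @param exclude Character vector of class names to drop (e.g. the
#'   minor-capsid exclusion experiment).
#' @return Character vector of class names.
#' @examples
#' class_list()
#' class_list(exclude = "Minor capsid")
#' @export
class_list <- function(include_others = TRUE, exclude = character()) {
  classes <- c("Major capsid", "Minor capsid", "Baseplate", "Major tail",
               "Minor tail", "Portal", "Tail fiber", "Tail sheath", "Collar",
               "Head-Tail joining")
  if (include_others) classes <- c(classes, "others")
  bad <- setdiff(exclude, classes)
  if (length(bad) > 0) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  setdiff(classes, exclude)
}

# Ambiguity mapping used under sanitize = "map": conservative one-letter
# substitutions; X is retained (it is skipped by k-mer windows but counts
# toward sequence length).
AMBIGUITY_MAP <- c(B = "D", Z = "E", U = "C", J = "L", O = "K")

sanitize_sequences <- function(ids, seqs, sanitize) {
  seqs <- toupper(seqs)
  seqs <- gsub("[\\s*-]", "", seqs, perl = TRUE)
  allowed <- c(AA_LETTERS, names(AMBIGUITY_MAP), "X")
  bad_letter <- function(s) {
    letters <- strsplit(s, "")[[1]]
    letters[!(letters %in% allowed)][1]
  }
  for (i in seq_along(seqs)) {
    b <- bad_letter(seqs[[i]])
    if (!is.na(b)) {
      stop("record '", ids[[i]], "' contains unrecognized letter '", b, "'")
    }
  }
  has_ambig <- grepl(paste0("[", paste(c(names(AMBIGUITY_MAP), "X"), collapse = ""), "]"), seqs)
  if (sanitize == "strict") {
    if (any(has_ambig)) {
      stop("record '", ids[which(has_ambig)[1]],
           "' contains ambiguity letters under sanitize = \"strict\"")
    }
  } else if (sanitize == "drop") {
    if (any(has_ambig)) {
      warning(sum(has_ambig), " record(s) with ambiguity letters dropped: ",
              paste(utils::head(ids[has_ambig], 5), collapse = ", "))
    }
    keep <- !has_ambig
    ids <- ids[keep]; seqs <- seqs[keep]
  } else { # map
    for (a in names(AMBIGUITY_MAP)) {
      seqs <- gsub(a, AMBIGUITY_MAP[[a]], seqs, fixed = TRUE)
    }
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning(sum(empty), " empty record(s) dropped")
    ids <- ids[!empty]; seqs <- seqs[!empty]
  }
  list(ids = ids, seqs = seqs)
}

#' Read protein records from a FASTA file
#'
#' @param path Path to a FASTA file (multi-line sequences accepted).
#' @param sanitize Ambiguity policy: `"map"` (default) replaces B->D, Z->E,
#'   U->C, J->L, O->K and keeps X (excluded from k-mer windows, counted in
#'   length); `"drop"` skips records containing any ambiguity letter with a
#'   warning; `"strict"` raises an error naming the offending record.
#'   Whitespace, gap characters and trailing stop `*` are always removed.
#' @return Tibble with columns `id` (first header token), `description`
#'   (remainder of the header) and `sequence`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 major capsid protein", "MKVL"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, sanitize = c("map", "drop", "strict")) {
  sanitize <- match.arg(sanitize)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), description = character(),
                          sequence = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))], collapse = ", "))
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  cleaned <- sanitize_sequences(ids, as.character(set), sanitize)
  keep <- match(cleaned$ids, ids)
  tibble::tibble(id = cleaned$ids, description = desc[keep],
                 sequence = unname(cleaned$seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with columns `id`, `sequence` and optionally
#'   `description` (appended to the header after a space when non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Read a two-column id/class label table
#'
#' The canonical labelling path: a headerless TSV `id<TAB>class`.
#'
#' @param path Path to the TSV file.
#' @param classes Valid class names; labels outside this set raise an error.
#'   `NULL` skips validation (any label accepted).
#' @return Tibble with columns `id`, `label`.
#' @export
read_label_table <- function(path, classes = class_list()) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- readr::read_tsv(path, col_names = c("id", "label"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (is.null(classes)) return(tab)
  bad <- setdiff(unique(tab$label), classes)
  if (length(bad) > 0) {
    stop("label table contains unknown class(es): ", paste(bad, collapse = ", "))
  }
  tab
}

#' Attach labels from a label table
#'
#' @param records Record tibble from [read_fasta()].
#' @param labels Tibble from [read_label_table()] (columns `id`, `label`).
#' @return `records` with a `label` column (`NA` where no label was given).
#' @export
label_from_table <- function(records, labels) {
  dplyr::left_join(records, labels, by = "id")
}

#' A small illustrative description-term table
#'
#' Maps each structural class to a handful of description substrings commonly
#' seen in public protein headers. This is a convenience default for
#' [label_from_terms()], not an exhaustive curation.
#'
#' @return Named list: class name -> character vector of lower-case terms.
#' @export
default_term_table <- function() {
  list(
    "Major capsid"      = c("major capsid", "major head protein", "coat protein"),
    "Minor capsid"      = c("minor capsid", "capsid decoration", "head decoration"),
    "Baseplate"         = c("baseplate"),
    "Major tail"        = c("major tail protein", "major tail subunit", "tail tube"),
    "Minor tail"        = c("minor tail", "tape measure"),
    "Portal"            = c("portal"),
    "Tail fiber"        = c("tail fiber", "tail fibre", "receptor binding protein"),
    "Tail sheath"       = c("tail sheath", "sheath protein"),
    "Collar"            = c("collar", "neck protein"),
    "Head-Tail joining" = c("head-tail", "head tail connector", "head completion",
                            "tail terminator")
  )
}

#' Assign class labels from description terms
#'
#' Case-insensitive substring matching of each record's description against a
#' class->terms table. A record matching terms of exactly one class receives
#' that label; records matching zero or two-plus classes stay unlabeled and
#' their counts are reported in a message.
#'
#' @param records Record tibble with a `description` column.
#' @param term_table Named list mapping class names to description substrings;
#'   default [default_term_table()].
#' @param classes Valid class names; every term-table name must be a member.
#' @return `records` with a `label` column (`NA_character_` where unmatched or
#'   ambiguous).
#' @examples
#' recs <- tibble::tibble(id = "p1", description = "major capsid protein",
#'                        sequence = "MKVL")
#' label_from_terms(recs)$label
#' @export
label_from_terms <- function(records, term_table = default_term_table(),
                             classes = class_list()) {
  stopifnot(length(term_table) > 0)
  bad <- setdiff(names(term_table), classes)
  if (length(bad) > 0) stop("term table names outside class list: ",
                            paste(bad, collapse = ", "))
  desc <- tolower(records$description)
  hits <- vapply(desc, function(d) {
    m <- vapply(term_table, function(terms) {
      any(vapply(terms, function(t) grepl(t, d, fixed = TRUE), logical(1)))
    }, logical(1))
    sum(m)
  }, integer(1))
  label <- rep(NA_character_, nrow(records))
  one <- hits == 1L
  if (any(one)) {
    label[one] <- vapply(desc[one], function(d) {
      m <- vapply(term_table, function(terms) {
        any(vapply(terms, function(t) grepl(t, d, fixed = TRUE), logical(1)))
      }, logical(1))
      names(term_table)[m]
    }, character(1))
  }
  n_ambig <- sum(hits >= 2L)
  n_none <- sum(hits == 0L)
  message(sum(one), " record(s) labeled; ", n_none, " unmatched; ",
          n_ambig, " ambiguous (left unlabeled)")
  records$label <- unname(label)
  records
}
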