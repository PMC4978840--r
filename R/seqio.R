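# FASTA reading/writing with an explicit policy for nonstandard residues.
# Parsing and serialisation are delegated to seqinr; this layer adds
# validation, the residue policy and the record data frame used downstream.

# map policy: standard ambiguity codes resolved to a concrete residue
RESIDUE_MAP <- c(B = "D", Z = "E", U = "C", O = "K", J = "L")

#' Construct a protein record table
#'
#' Records are plain data frames with columns `id`, `description`, `sequence`
#' (cleaned, over the 20 standard one-letter codes) and `raw_length` (residue
#' count before cleaning). All pipeline functions that accept sequences take
#' this shape.
#'
#' @param id character vector of non-empty identifiers.
#' @param sequence character vector of cleaned sequences.
#' @param description optional free-text descriptions (default "").
#' @param raw_length residue counts before cleaning (default `nchar(sequence)`).
#' @return a `data.frame` with one row per record.
#' @export
protein_records <- function(id, sequence, description = "", raw_length = nchar(sequence)) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (any(!nzchar(sequence))) stop("sequences must be non-empty")
  bad <- vapply(strsplit(sequence, ""), function(ch) any(!ch %in% AA20), logical(1))
  if (any(bad)) {
    stop(sprintf("sequence for record '%s' contains residues outside the 20-letter alphabet",
                 id[which(bad)[1]]))
  }
  data.frame(id = id,
             description = rep_len(as.character(description), length(id)),
             sequence = sequence,
             raw_length = as.integer(rep_len(raw_length, length(id))),
             stringsAsFactors = FALSE)
}

# Apply a residue policy to one raw (uppercased) sequence. Returns the cleaned
# sequence, possibly empty. strict violations name the record and residue.
clean_sequence <- function(seq, policy, id = "<unnamed>") {
  ch <- strsplit(seq, "")[[1]]
  nonstd <- !ch %in% AA20
  if (!any(nonstd)) return(seq)
  if (policy == "strict") {
    stop(sprintf("record '%s': nonstandard residue(s) %s under policy 'strict'",
                 id, paste(sQuote(unique(ch[nonstd])), collapse = ", ")))
  }
  if (policy == "map") {
    mapped <- RESIDUE_MAP[ch]
    ch <- ifelse(is.na(mapped), ch, unname(mapped))
  }
  paste(ch[ch %in% AA20], collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, then cleaned according to `policy`:
#' \describe{
#'   \item{strict}{any residue outside the 20 standard codes is an error,
#'     naming the record and the offending character(s);}
#'   \item{drop}{nonstandard residues are removed;}
#'   \item{map}{ambiguity codes are resolved (B to D, Z to E, U to C, O to K,
#'     J to L) and anything still nonstandard (X, gaps, stops) is removed.}
#' }
#' `map` is the default: it keeps the most signal while guaranteeing the
#' 20-letter alphabet the encoders require. Records whose cleaned sequence is
#' empty are omitted with a warning; duplicated ids are kept (downstream
#' stages key on position, not id) and reported via `message()`.
#'
#' @param path path to a FASTA file.
#' @param policy one of `"map"`, `"strict"`, `"drop"`.
#' @return a record `data.frame` as produced by [protein_records()], in file
#'   order, with `raw_length` the pre-cleaning residue count.
#' @export
read_fasta <- function(path, policy = c("map", "strict", "drop")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop(sprintf("empty FASTA file: %s", path))
  if (!startsWith(nonblank[1], ">")) {
    stop(sprintf("malformed FASTA (%s): sequence line before any header", path))
  }
  entries <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                whole.header = TRUE)
  headers <- vapply(entries, function(e) attr(e, "name"), character(1))
  raw <- toupper(vapply(entries, function(e) gsub("[[:space:]]", "", as.character(e)),
                        character(1)))
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- trimws(sub("^[^[:space:]]+[[:space:]]?", "", headers))
  if (any(!nzchar(ids))) stop(sprintf("malformed FASTA (%s): empty header id", path))
  cleaned <- character(length(raw))
  for (i in seq_along(raw)) cleaned[i] <- clean_sequence(raw[i], policy, ids[i])
  empty <- !nzchar(cleaned)
  if (any(empty)) {
    warning(sprintf("omitting %d record(s) whose cleaned sequence is empty: %s",
                    sum(empty), paste(ids[empty], collapse = ", ")))
  }
  keep <- !empty
  dup <- unique(ids[keep][duplicated(ids[keep])])
  if (length(dup)) {
    message(sprintf("duplicate FASTA id(s) kept: %s", paste(dup, collapse = ", ")))
  }
  protein_records(id = ids[keep], sequence = cleaned[keep],
                  description = desc[keep], raw_length = nchar(raw)[keep])
}

#' Write protein records to a FASTA file
#'
#' Output round-trips: `read_fasta(write_fasta(records), policy = "strict")`
#' reproduces ids and sequences exactly.
#'
#' @param records a record `data.frame` ([protein_records()]); must be non-empty.
#' @param path output file path.
#' @param width sequence line width in residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (nrow(records) == 0L) stop("no records to write")
  if (width < 1) stop("width must be >= 1")
  nm <- ifelse(nzchar(records$description),
               paste(records$id, records$description), records$id)
  seqinr::write.fasta(lapply(records$sequence, function(s) strsplit(s, "")[[1]]),
                      names = nm, file.out = path, nbchar = width)
  invisible(path)
}
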