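# The eight three-class amino-acid partitions that drive the CTD encoders.
# Partitions follow the SVM-Prot/PROFEAT lineage; class order is part of the
# public feature-ordering contract (features are laid out C1,C2,C3,T12,T13,
# T23,D1,D2,D3 per property, properties in the order below).

GROUPING_SPECS <- list(
  hydrophobicity = list(
    labels  = c("polar", "neutral", "hydrophobic"),
    classes = c("RKEDQN", "GASTPHY", "CLVIMFW")),
  vdw_volume = list(
    labels  = c("small", "medium", "large"),
    classes = c("GASTPDC", "NVEQIL", "MHKFRYW")),
  polarity = list(
    labels  = c("low", "medium", "high"),
    classes = c("LIFWCMVY", "PATGS", "HQRKNED")),
  polarizability = list(
    labels  = c("low", "medium", "high"),
    classes = c("GASDT", "CPNVEQIL", "KMHFRYW")),
  charge = list(
    labels  = c("positive", "neutral", "negative"),
    classes = c("KR", "ANCQGHILMFPSTWYV", "DE")),
  surface_tension = list(
    labels  = c("low", "medium", "high"),
    classes = c("GQDNAHR", "KTSEC", "ILMFPWYV")),
  secondary_structure = list(
    labels  = c("helix", "strand", "coil"),
    classes = c("EALMQKRH", "VIYCWFT", "GNPSD")),
  solvent_accessibility = list(
    labels  = c("buried", "exposed", "intermediate"),
    classes = c("ALFCGIVW", "RKQEND", "MSPTHY"))
)

new_grouping <- function(name, classes, labels) {
  classes <- lapply(classes, function(s) strsplit(s, "")[[1]])
  all_res <- unlist(classes)
  if (anyDuplicated(all_res)) {
    stop(sprintf("grouping '%s': classes are not disjoint", name))
  }
  if (!setequal(all_res, AA20)) {
    stop(sprintf("grouping '%s': classes do not cover the 20 standard amino acids", name))
  }
  structure(list(name = name, classes = classes, labels = labels),
            class = "aa_grouping")
}

#' @export
print.aa_grouping <- function(x, ...) {
  cat(sprintf("Amino-acid grouping '%s':\n", x$name))
  for (j in 1:3) {
    cat(sprintf("  class %d (%s): %s\n", j, x$labels[j],
                paste(x$classes[[j]], collapse = "")))
  }
  invisible(x)
}

#' The eight default physicochemical property groupings
#'
#' Returns the ordered list of three-class amino-acid partitions used by the
#' 188D encoder: hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, surface tension, secondary-structure propensity and
#' solvent accessibility. Each grouping partitions the 20 standard residues
#' into three disjoint classes; both the property order and the class order
#' within a property are fixed, because feature positions depend on them.
#' The same tables ship as a plain-text config
#' (`system.file("extdata", "property_groupings.txt", package = "gpcr188")`)
#' and can be replaced wholesale via [read_property_table()].
#'
#' @return a named list of 8 `aa_grouping` objects.
#' @export
default_groupings <- function() {
  mapply(function(name, spec) new_grouping(name, spec$classes, spec$labels),
         names(GROUPING_SPECS), GROUPING_SPECS, SIMPLIFY = FALSE)
}

#' Map a sequence to its class string under one grouping
#'
#' Position i of the result is the class index ("1", "2" or "3") of residue i.
#'
#' @param sequence a sequence over the 20 standard one-letter codes.
#' @param grouping an `aa_grouping`.
#' @return a string over \{1,2,3\} of the same length as `sequence`.
#' @export
class_string <- function(sequence, grouping) {
  stopifnot(inherits(grouping, "aa_grouping"))
  lut <- grouping_lut(grouping)
  ch <- strsplit(sequence, "")[[1]]
  idx <- lut[match(ch, AA20)]
  if (anyNA(idx)) {
    stop(sprintf("residue(s) outside the 20-letter alphabet: %s",
                 paste(unique(ch[is.na(idx)]), collapse = ", ")))
  }
  paste(idx, collapse = "")
}

# integer class index per residue, in AA20 order
grouping_lut <- function(grouping) {
  lut <- integer(20)
  for (j in 1:3) lut[match(grouping$classes[[j]], AA20)] <- j
  if (any(lut == 0L)) stop("grouping does not cover the alphabet")
  lut
}

#' Read property groupings from a plain-text config file
#'
#' The format mirrors the shipped default table: a `[property_name]` section
#' header followed by three lines `class<j> <label> <residues>`; blank lines
#' and `#` comments are ignored. Every grouping must be a disjoint cover of
#' the 20 standard amino acids; section order and class order define the
#' feature layout.
#'
#' @param path path to a groupings config file.
#' @return a named list of `aa_grouping` objects, in file order.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("property table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  groupings <- list()
  cur <- NULL
  cur_classes <- character(3)
  cur_labels <- character(3)
  flush <- function() {
    if (is.null(cur)) return()
    if (any(!nzchar(cur_classes))) {
      stop(sprintf("property '%s': fewer than 3 classes defined", cur))
    }
    groupings[[cur]] <<- new_grouping(cur, as.list(cur_classes), cur_labels)
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      cur <- gsub("^\\[|\\]$", "", ln)
      cur_classes <- character(3)
      cur_labels <- character(3)
    } else {
      m <- regmatches(ln, regexec("^class([123])[[:space:]]+([^[:space:]]+)[[:space:]]+([A-Za-z]+)$", ln))[[1]]
      if (length(m) == 0L || is.null(cur)) {
        stop(sprintf("cannot parse property-table line: '%s'", ln))
      }
      j <- as.integer(m[2])
      cur_labels[j] <- m[3]
      cur_classes[j] <- toupper(m[4])
    }
  }
  flush()
  if (length(groupings) == 0L) stop("property table defines no groupings")
  groupings
}
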