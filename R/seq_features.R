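CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein sequence
#'
#' A 1-letter amino-acid string with 1-based residue positions, restricted to
#' the 20 canonical residues.
#'
#' @param id Sequence identifier.
#' @param residues Amino-acid string (1-letter codes).
#' @return A `protein_sequence` object.
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), CANONICAL_AA)
  if (length(bad)) {
    stop(sprintf("non-canonical residues in '%s': %s", id,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

# per-residue charge: R/K = +1, D/E = -1, everything else (incl. H) = 0
residue_charges <- function(chars) {
  (chars %in% c("R", "K")) - (chars %in% c("D", "E"))
}

#' Net charge per residue (NCPR) sliding-window profile
#'
#' Charge profile of a sequence with arginine and lysine counted +1,
#' aspartate and glutamate -1, and all other residues (including histidine)
#' 0, averaged over a sliding window. Values are reported at the window
#' center position (for the default 5-residue window, a window starting at
#' residue `i` is reported at `i + 2`); terminal positions without a full
#' window are omitted, not padded.
#'
#' @param seq A [protein_sequence()].
#' @param window Window size in residues (odd, default 5).
#' @return An `ncpr_profile`: data frame with `center` (1-based residue
#'   index) and `ncpr` (in `[-1, 1]`); the window size is kept as an
#'   attribute.
#' @examples
#' ncpr_profile(protein_sequence("x", "RKDDE"))$ncpr  # (2 - 3) / 5
#' @export
ncpr_profile <- function(seq, window = 5L) {
  stopifnot(inherits(seq, "protein_sequence"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd number of residues", call. = FALSE)
  }
  L <- length(seq)
  if (L < window) {
    stop(sprintf("sequence '%s' (%d aa) shorter than window (%d)",
                 seq$id, L, window), call. = FALSE)
  }
  q <- residue_charges(seq_chars(seq))
  csum <- cumsum(c(0, q))
  starts <- seq_len(L - window + 1L)
  vals <- (csum[starts + window] - csum[starts]) / window
  out <- data.frame(center = starts + (window - 1L) %/% 2L, ncpr = vals)
  attr(out, "window") <- window
  attr(out, "id") <- seq$id
  class(out) <- c("ncpr_profile", "data.frame")
  out
}

#' Residue-class composition of a region
#'
#' Counts, within a residue interval, the residue classes relevant to
#' condensation mutagenesis: tyrosine (Y), basic (R/K), acidic (D/E), polar
#' amide (Q/N), hydrophobic (V/M/F), and everything else.
#'
#' @param seq A [protein_sequence()].
#' @param region 1-based inclusive `(start, end)` interval; defaults to the
#'   whole sequence.
#' @return Data frame with `class`, `count`, `fraction` (of the region
#'   length).
#' @export
residue_class_composition <- function(seq, region = c(1L, length(seq))) {
  stopifnot(inherits(seq, "protein_sequence"))
  region <- as.integer(region)
  L <- length(seq)
  if (length(region) != 2L || region[1] < 1L || region[2] > L ||
      region[1] > region[2]) {
    stop(sprintf("invalid region [%s] for a %d-aa sequence",
                 paste(region, collapse = ", "), L), call. = FALSE)
  }
  chars <- seq_chars(seq)[region[1]:region[2]]
  classes <- list(Y = "Y", RK = c("R", "K"), DE = c("D", "E"),
                  QN = c("Q", "N"), VMF = c("V", "M", "F"))
  counts <- vapply(classes, function(cl) sum(chars %in% cl), 0L)
  counts <- c(counts, other = length(chars) - sum(counts))
  data.frame(class = names(counts), count = unname(counts),
             fraction = unname(counts) / length(chars))
}

#' Residue-substitution rule
#'
#' A named residue-to-residue mapping applied within a region, e.g. the
#' "CTD-Y to S" construct that replaces every tyrosine in the C-terminal
#' domain with serine.
#'
#' @param name Rule name, recorded in the mutant id.
#' @param region 1-based inclusive interval the rule acts on.
#' @param mapping Named character vector: `c(Y = "S")`, `c(R = "G", K = "G")`,
#'   ... Keys and replacements must be single canonical residues. An empty
#'   mapping is the identity.
#' @return A `substitution_rule` object.
#' @export
substitution_rule <- function(name, region, mapping) {
  stopifnot(is.character(name), length(name) == 1L)
  region <- as.integer(region)
  stopifnot(length(region) == 2L, region[1] >= 1L, region[1] <= region[2])
  mapping <- unlist(mapping)
  if (length(mapping)) {
    keys <- names(mapping)
    if (is.null(keys) || any(nchar(keys) != 1L) ||
        !all(keys %in% CANONICAL_AA)) {
      stop("mapping keys must be single canonical residues", call. = FALSE)
    }
    if (any(nchar(mapping) != 1L) || !all(mapping %in% CANONICAL_AA)) {
      stop("replacements must be single canonical residues", call. = FALSE)
    }
  }
  structure(list(name = name, region = region, mapping = mapping),
            class = "substitution_rule")
}

#' Apply a substitution rule to a sequence
#'
#' Every residue within the rule's region that matches a mapping key is
#' replaced; residues outside the region are untouched. The output id
#' records the rule name. Sequence length is unchanged.
#'
#' @param seq A [protein_sequence()].
#' @param rule A [substitution_rule()].
#' @return A new `protein_sequence`.
#' @examples
#' s <- protein_sequence("x", "AYRYK")
#' apply_substitution_rule(s, substitution_rule("Y to S", c(1, 5), c(Y = "S")))
#' @export
apply_substitution_rule <- function(seq, rule) {
  stopifnot(inherits(seq, "protein_sequence"),
            inherits(rule, "substitution_rule"))
  L <- length(seq)
  if (rule$region[2] > L) {
    stop(sprintf("rule region [%d, %d] exceeds sequence length %d",
                 rule$region[1], rule$region[2], L), call. = FALSE)
  }
  chars <- seq_chars(seq)
  if (length(rule$mapping)) {
    span <- rule$region[1]:rule$region[2]
    hit <- chars[span] %in% names(rule$mapping)
    chars[span][hit] <- unname(rule$mapping[chars[span][hit]])
  }
  protein_sequence(paste0(seq$id, "|", rule$name),
                   paste(chars, collapse = ""))
}

#' Deletion variant of a sequence
#'
#' Removes a 1-based inclusive residue interval (e.g. a domain truncation
#' such as \eqn{\Delta}1–127). Deleting the whole sequence is an error.
#'
#' @param seq A [protein_sequence()].
#' @param interval 1-based inclusive `(start, end)` to remove.
#' @return A new `protein_sequence` whose id records the deletion.
#' @export
deletion_variant <- function(seq, interval) {
  stopifnot(inherits(seq, "protein_sequence"))
  interval <- as.integer(interval)
  L <- length(seq)
  if (length(interval) != 2L || interval[1] < 1L || interval[2] > L ||
      interval[1] > interval[2]) {
    stop(sprintf("invalid deletion interval [%s] for a %d-aa sequence",
                 paste(interval, collapse = ", "), L), call. = FALSE)
  }
  if (interval[1] == 1L && interval[2] == L) {
    stop("deletion would remove the whole sequence", call. = FALSE)
  }
  chars <- seq_chars(seq)[-(interval[1]:interval[2])]
  protein_sequence(sprintf("%s|d%d-%d", seq$id, interval[1], interval[2]),
                   paste(chars, collapse = ""))
}

#' Canonical C-terminal-domain mutagenesis rules
#'
#' The residue-class substitution constructs used to probe which residues of
#' the YBX1 C-terminal disordered domain (residues 128–324) drive
#' condensation: Y to S, Y to A, R/K to G, D/E to G, Q/N to G, and V/M/F to
#' A.
#'
#' @param region CTD interval, default `c(128, 324)`.
#' @return Named list of [substitution_rule()] objects.
#' @export
ctd_substitution_rules <- function(region = c(128L, 324L)) {
  list(
    `Y to S` = substitution_rule("CTD-Y to S", region, c(Y = "S")),
    `Y to A` = substitution_rule("CTD-Y to A", region, c(Y = "A")),
    `RK to G` = substitution_rule("CTD-RK to G", region, c(R = "G", K = "G")),
    `DE to G` = substitution_rule("CTD-DE to G", region, c(D = "G", E = "G")),
    `QN to G` = substitution_rule("CTD-QN to G", region, c(Q = "G", N = "G")),
    `VMF to A` = substitution_rule("CTD-VMF to A", region,
                                   c(V = "A", M = "A", F = "A")))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named list of [protein_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA not found: %s", path),
                               call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(aa), function(i) {
    protein_sequence(sub("\\s.*$", "", names(aa)[i]), as.character(aa[[i]]))
  })
  names(out) <- vapply(out, function(s) s$id, "")
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs A [protein_sequence()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  aa <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(aa) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
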