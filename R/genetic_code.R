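# Codon/anticodon algebra and wobble-rule decoding predictions.
# All sequences here are RNA (U, never T); DNA appears only at trace I/O.

#' RNA alphabet
#'
#' The four unmodified RNA bases, in the fixed internal order used for codon
#' box members and channel-independent iteration.
#'
#' @export
RNA_BASES <- c("A", "C", "G", "U")

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

.split_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @keywords internal
#' @noRd
validate_rna_triple <- function(x, what = "codon", allow_inosine_34 = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
  x <- toupper(x)
  b <- .split_bases(x)
  if (length(b) != 3L) {
    stop(sprintf("%s must have exactly 3 bases, got '%s'", what, x),
         call. = FALSE)
  }
  ok <- b %in% RNA_BASES
  if (allow_inosine_34) ok[1] <- ok[1] || b[1] == "I"
  if (!all(ok)) {
    hint <- if (any(b == "T")) " (RNA alphabet: use U, not T)" else ""
    stop(sprintf("%s '%s' contains non-RNA characters%s", what, x, hint),
         call. = FALSE)
  }
  x
}

#' Codon targeted by an anticodon
#'
#' Returns the codon decoded by Watson-Crick pairing with an anticodon,
#' i.e. the reverse complement read 5'-3'. The anticodon is written 5'-3' as
#' positions 34, 35, 36; pairing is antiparallel, so position 36 complements
#' codon position 1, 35 pairs 2, and 34 (the wobble base) pairs codon
#' position 3.
#'
#' @param anticodon Three-base RNA string (positions 34-36, 5'-3'),
#'   e.g. `"ACG"`.
#' @return Three-base RNA codon string, e.g. `"CGU"`.
#' @examples
#' targeted_codon("AAA") # "UUU" (Phe)
#' targeted_codon("ACG") # "CGU" (Arg)
#' @seealso [anticodon_for()] for the inverse.
#' @export
targeted_codon <- function(anticodon) {
  ac <- validate_rna_triple(anticodon, what = "anticodon")
  paste(.rna_complement[rev(.split_bases(ac))], collapse = "")
}

#' Anticodon that targets a codon
#'
#' Inverse of [targeted_codon()]: the anticodon whose Watson-Crick pairing
#' reads the given codon. Reverse complementation is an involution, so the
#' two functions form a bijection over all 64 triples.
#'
#' @param codon Three-base RNA codon string.
#' @return Three-base RNA anticodon string (positions 34-36, 5'-3').
#' @examples
#' anticodon_for("UUU") # "AAA"
#' @export
anticodon_for <- function(codon) {
  cd <- validate_rna_triple(codon, what = "codon")
  paste(.rna_complement[rev(.split_bases(cd))], collapse = "")
}

#' Wobble base of an anticodon
#'
#' Position 34 is the 5'-most anticodon base (first character in the 5'-3'
#' notation used throughout the package).
#'
#' @param anticodon Three-base anticodon string; `"I"` is accepted at
#'   position 34 (inosine).
#' @return Single character.
#' @export
wobble_base <- function(anticodon) {
  ac <- validate_rna_triple(anticodon, what = "anticodon",
                            allow_inosine_34 = TRUE)
  substr(ac, 1L, 1L)
}

#' Codon box of a codon
#'
#' The codon box is the set of four codons sharing the first two bases.
#' Its strength is the number of G or C among those two bases (0-2): "strong"
#' boxes (strength 2) are those where the two Watson-Crick pairs formed at
#' codon positions 1 and 2 are both G:C.
#'
#' @param codon Three-base RNA codon string.
#' @return An object of class `codon_box`: list with `prefix` (two bases),
#'   `members` (four codons, third base in A,C,G,U order) and `strength`
#'   (integer 0-2).
#' @examples
#' codon_box("CCU")$strength # 2
#' codon_box("CAU")$strength # 1
#' @export
codon_box <- function(codon) {
  cd <- validate_rna_triple(codon, what = "codon")
  prefix <- substr(cd, 1L, 2L)
  structure(
    list(
      prefix = prefix,
      members = paste0(prefix, RNA_BASES),
      strength = sum(.split_bases(prefix) %in% c("G", "C"))
    ),
    class = "codon_box"
  )
}

#' @export
print.codon_box <- function(x, ...) {
  cat(sprintf("codon box %s_ (strength %d): %s\n",
              x$prefix, x$strength, paste(x$members, collapse = " ")))
  invisible(x)
}

# Built-in rule sets. Each mapping lists, for a wobble base at anticodon
# position 34, the codon third bases it can read, strongest pairing first.
# The preference order is ordinal only; no pairing energies are modelled.
.builtin_rules <- function(name) {
  crick <- list(
    A = "U",
    C = "G",
    G = c("C", "U"),
    U = c("A", "G"),
    I = c("U", "C", "A")
  )
  expanded <- crick
  expanded$A <- c("U", "C", "G", "A") # in vivo/in vitro preference order
  switch(name,
    crick_original = list(name = name, mapping = crick,
                          box_strength_gate = NA_integer_),
    expanded_a34 = list(name = name, mapping = expanded,
                        box_strength_gate = NA_integer_),
    inosine = list(name = name, mapping = crick,
                   box_strength_gate = NA_integer_),
    two_out_of_three = list(name = name, mapping = expanded,
                            fallback = crick, box_strength_gate = 2L)
  )
}

#' Wobble decoding rule sets
#'
#' Built-in rule sets mapping the anticodon position-34 base to the codon
#' third bases it can read, in decreasing pairing-preference order:
#'
#' * `crick_original`: the classical wobble rules. A34 reads only U3;
#'   I34 reads U, C and A.
#' * `expanded_a34`: unmodified A34 allowed to read all four third bases in
#'   the order U > C > G > A.
#' * `inosine`: alias emphasizing the I34 rules (U, C, A); other bases as in
#'   the classical rules.
#' * `two_out_of_three`: when both of the first two codon-anticodon pairs are
#'   G:C (box strength 2), third-position discrimination is relaxed and all
#'   four box members are predicted; in weaker boxes it falls back to the
#'   classical rules.
#'
#' @param name Rule set name.
#' @return An object of class `wobble_rule_set`: list with `name`, `mapping`
#'   (wobble base -> ordered codon-3 bases), `box_strength_gate` and, for
#'   `two_out_of_three`, the `fallback` mapping.
#' @seealso [load_wobble_rules()] to read a custom rule set from YAML,
#'   [predicted_codon_set()] to apply one.
#' @export
wobble_rules <- function(name = c("crick_original", "expanded_a34",
                                  "inosine", "two_out_of_three")) {
  if (length(name) != 1L || !name %in% c("crick_original", "expanded_a34",
                                         "inosine", "two_out_of_three")) {
    name <- tryCatch(match.arg(name),
                     error = function(e) stop("unknown rule-set name: ",
                                              paste(name, collapse = ","),
                                              call. = FALSE))
  }
  structure(.builtin_rules(name), class = "wobble_rule_set")
}

#' Load a custom wobble rule set from a YAML file
#'
#' The file maps wobble bases to ordered codon third bases, e.g.
#' \preformatted{
#' name: my_rules
#' mapping:
#'   A: [U, C]
#'   I: [U, C, A]
#' box_strength_gate: 2
#' }
#' `box_strength_gate` is optional; when present, boxes at or above the gate
#' predict all four members (as in `two_out_of_three`).
#'
#' @param path Path to the YAML file.
#' @return A `wobble_rule_set`.
#' @export
load_wobble_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$mapping)) stop("rule file must contain a 'mapping' entry",
                                 call. = FALSE)
  mapping <- lapply(raw$mapping, function(v) toupper(as.character(v)))
  for (wb in names(mapping)) {
    v <- mapping[[wb]]
    if (anyDuplicated(v)) {
      stop(sprintf("rule for wobble base %s lists a codon-3 base twice", wb),
           call. = FALSE)
    }
    if (!all(v %in% RNA_BASES)) {
      stop(sprintf("rule for wobble base %s contains non-RNA bases", wb),
           call. = FALSE)
    }
  }
  structure(
    list(
      name = if (is.null(raw$name)) "custom" else raw$name,
      mapping = mapping,
      fallback = mapping,
      box_strength_gate = if (is.null(raw$box_strength_gate)) NA_integer_
                          else as.integer(raw$box_strength_gate)
    ),
    class = "wobble_rule_set"
  )
}

#' Codons in a box predicted to be decoded by a wobble base
#'
#' Applies a wobble rule set to a position-34 base within a codon box and
#' returns the decodable codons in the rule set's stated preference order
#' (strongest pairing first). Under `two_out_of_three`, boxes with two G/C
#' prefix bases return all four members; weaker boxes use the classical
#' rules.
#'
#' @param wobble34 Single base at anticodon position 34: A, C, G, U or I.
#' @param box A `codon_box` (see [codon_box()]).
#' @param rules A `wobble_rule_set` or a rule-set name accepted by
#'   [wobble_rules()].
#' @return Character vector of codons, a subset of `box$members`.
#' @examples
#' predicted_codon_set("A", codon_box("UUU"), "crick_original") # "UUU"
#' predicted_codon_set("I", codon_box("CGU"), "inosine")        # CGU CGC CGA
#' @export
predicted_codon_set <- function(wobble34, box, rules = "crick_original") {
  if (is.character(rules)) rules <- wobble_rules(rules)
  if (!inherits(rules, "wobble_rule_set")) {
    stop("rules must be a wobble_rule_set or a rule-set name", call. = FALSE)
  }
  if (!inherits(box, "codon_box")) stop("box must be a codon_box",
                                        call. = FALSE)
  wobble34 <- toupper(wobble34)
  if (!is.character(wobble34) || length(wobble34) != 1L ||
      !wobble34 %in% c(RNA_BASES, "I")) {
    stop("wobble34 must be one of A, C, G, U, I", call. = FALSE)
  }
  gate <- rules$box_strength_gate
  mapping <- rules$mapping
  if (!is.na(gate)) {
    if (box$strength >= gate) {
      allowed <- mapping[[wobble34]]
      allowed <- unique(c(allowed, setdiff(c("U", "C", "G", "A"), allowed)))
    } else {
      mapping <- if (is.null(rules$fallback)) mapping else rules$fallback
      allowed <- mapping[[wobble34]]
    }
  } else {
    allowed <- mapping[[wobble34]]
  }
  if (is.null(allowed)) {
    stop(sprintf("rule set '%s' has no entry for wobble base %s",
                 rules$name, wobble34), call. = FALSE)
  }
  paste0(box$prefix, allowed)
}
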