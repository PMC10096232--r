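# The 12-state joint sequence-structure alphabet: 4 bases x 3 structural
# roles (unpaired / opening partner / closing partner), plus 0 for gap.
# State index = (base - 1) * 3 + role, bases ordered A,C,G,U and roles
# unpaired(1), open(2), close(3).

ROLES <- c("unpaired", "open", "close")
ROLE_CHAR <- c(".", "(", ")")

state_index <- function(base, role) {
  b <- match(base, RNA_BASES)
  r <- match(role, ROLES)
  if (anyNA(b)) stop("encode12: ambiguity codes cannot be encoded; resolve or skip")
  (b - 1L) * 3L + r
}

state_base <- function(state) {
  out <- rep(NA_character_, length(state))
  nz <- !is.na(state) & state > 0L
  out[nz] <- RNA_BASES[(state[nz] - 1L) %/% 3L + 1L]
  out
}

state_role <- function(state) {
  out <- rep(NA_character_, length(state))
  nz <- !is.na(state) & state > 0L
  out[nz] <- ROLES[(state[nz] - 1L) %% 3L + 1L]
  out
}

#' Encode a record in the 12-state joint alphabet
#'
#' Position `i` maps to `(base, unpaired)` when unpaired, `(base, open)` when
#' `i` is the 5' partner of its pair, and `(base, close)` when it is the 3'
#' partner. The encoding is exactly invertible given the pairing is nested.
#'
#' @param record A [seq_struct_record()].
#' @return Integer vector of states in `1..12` with attributes `"id"` and
#'   `"partner"` (the per-position partner index, `NA` when unpaired).
#' @export
encode12 <- function(record) {
  stopifnot(inherits(record, "SeqStructRecord"))
  ch <- seq_chars(record)
  if (any(!ch %in% RNA_BASES)) {
    stop(sprintf("%s: ambiguity codes cannot be encoded", record$id))
  }
  n <- length(ch)
  role <- rep("unpaired", n)
  if (nrow(record$pairs) > 0L) {
    role[record$pairs[, 1L]] <- "open"
    role[record$pairs[, 2L]] <- "close"
  }
  st <- state_index(ch, role)
  attr(st, "id") <- record$id
  attr(st, "partner") <- partner_vector(record$pairs, n)
  st
}

#' Decode a 12-state vector back to a record
#'
#' Inverse of [encode12()]: bases are read off directly and the nested pair
#' set is reconstructed by matching open and close roles with a stack.
#'
#' @param states Integer state vector (values `1..12`).
#' @param id Record id for the reconstructed record.
#' @param region Region label.
#' @return A [seq_struct_record()].
#' @export
decode12 <- function(states, id = "decoded", region = "OTHER") {
  base <- state_base(states)
  role <- state_role(states)
  db <- paste(ROLE_CHAR[match(role, ROLES)], collapse = "")
  seq_struct_record(id, paste(base, collapse = ""),
                    pairs = dotbracket_to_pairs(db), region = region)
}

# Human-readable state labels like "A(", used in reports.
state_label <- function(state) {
  out <- rep("-", length(state))
  nz <- !is.na(state) & state > 0L
  out[nz] <- paste0(state_base(state[nz]),
                    ROLE_CHAR[match(state_role(state[nz]), ROLES)])
  out
}
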