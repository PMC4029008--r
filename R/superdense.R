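#' Bell basis states
#'
#' The four orthonormal two-qubit Bell states, labelled by two classical
#' bits: `|psi_00> = (|00> + |11>)/sqrt(2)`, `|psi_01> = (|01> + |10>)/sqrt(2)`,
#' `|psi_10> = (|00> - |11>)/sqrt(2)`, `|psi_11> = (|01> - |10>)/sqrt(2)`.
#'
#' @param bits Two classical bits as a string (`"00"`, `"01"`, `"10"`, `"11"`)
#'   or an integer vector of length 2.
#' @return A two-qubit [quantum_state()].
#' @examples
#' bell_state("00")$amplitudes
#' @export
bell_state <- function(bits) {
  b <- parse_bits(bits, 2L)
  s <- 1 / sqrt(2)
  amp <- switch(paste(b, collapse = ""),
    "00" = c(s, 0, 0, s),
    "01" = c(0, s, s, 0),
    "10" = c(s, 0, 0, -s),
    "11" = c(0, s, -s, 0)
  )
  quantum_state(2L, complex(real = amp))
}

#' Superdense coding: encode two classical bits on one qubit
#'
#' Starting from the shared pair `|psi_00>`, the sender applies `Z^b1 X^b2`
#' to their (first) qubit; the resulting state is the Bell state labelled by
#' the message (up to a global phase for `"11"`).
#'
#' @param bits Two classical bits (string or length-2 integer vector).
#' @return A two-qubit [quantum_state()] carrying the message.
#' @examples
#' superdense_decode(superdense_encode("10"))$bits  # "10"
#' @export
superdense_encode <- function(bits) {
  b <- parse_bits(bits, 2L)
  state <- bell_state("00")
  a <- state$amplitudes  # order |00>, |01>, |10>, |11>
  if (b[[2]] == 1) a <- a[c(3, 4, 1, 2)]            # X on first qubit
  if (b[[1]] == 1) a[3:4] <- -a[3:4]                # Z on first qubit
  state$amplitudes <- a
  state
}

#' Superdense coding: decode a two-qubit state
#'
#' Reverse Bell measurement: projects onto the Bell basis and returns the
#' most probable two-bit label. For a true (possibly globally phased) Bell
#' state the outcome is deterministic; otherwise the argmax outcome is
#' returned with its probability and flagged non-deterministic.
#'
#' @param state A two-qubit [quantum_state()].
#' @return A list with `bits` (string), `probability` and `deterministic`.
#' @export
superdense_decode <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  if (state$n_qubits != 2L) abort("Superdense decoding needs a 2-qubit state.")
  labels <- c("00", "01", "10", "11")
  probs <- vapply(labels, function(b) {
    Mod(sum(Conj(bell_state(b)$amplitudes) * state$amplitudes))^2
  }, numeric(1))
  best <- which.max(probs)
  list(bits = labels[[best]],
       probability = unname(probs[[best]]),
       deterministic = abs(probs[[best]] - 1) < 1e-10)
}

#' IP3R monomer conformational register
#'
#' Three occupancy bits describing one IP3R monomer: the IP3 binding site,
#' the high-affinity Ca2+ (activation) site and the low-affinity Ca2+
#' (inhibition) site, with 1 = bound. `|100>` is the activation-primed but
#' closed conformation; `|110>` is the conducting conformation.
#'
#' @param bits Three bits as a string (e.g. `"110"`) or length-3 integer
#'   vector.
#' @return An object of class `monomer_register`.
#' @export
monomer_register <- function(bits) {
  b <- parse_bits(bits, 3L)
  structure(list(bits = b, label = paste(b, collapse = "")),
            class = "monomer_register")
}

#' @export
print.monomer_register <- function(x, ...) {
  cat("<monomer_register> |", x$label, ">  (IP3, high-affinity Ca, low-affinity Ca)\n",
      sep = "")
  invisible(x)
}

#' Conformational indicator function theta
#'
#' Returns 1 exactly for the conducting conformation `|110>` (IP3 bound,
#' high-affinity Ca2+ bound, low-affinity site free) and 0 for every other
#' 3-bit configuration, unless a different conducting set is configured.
#'
#' @param reg A [monomer_register()] (or bits accepted by it).
#' @param conducting Character vector of conducting bit strings
#'   (default `"110"`).
#' @return 0 or 1.
#' @examples
#' theta_conformation("110")  # 1
#' theta_conformation("100")  # 0: primed but closed
#' @export
theta_conformation <- function(reg, conducting = "110") {
  if (!inherits(reg, "monomer_register")) reg <- monomer_register(reg)
  as.integer(reg$label %in% conducting)
}

#' Number of primed monomer configurations to maintain
#'
#' The falling-factorial count `Mn! / (Mn - 1)! = Mn` of superposed
#' activation-primed configurations a channel with `Mn` monomers must hold;
#' for the tetrameric IP3R, `Mn = 4` gives 4.
#'
#' @param Mn Number of monomers, integer >= 1.
#' @return Integer count.
#' @examples
#' count_primed_configurations(4)  # 4
#' @export
count_primed_configurations <- function(Mn) {
  Mn <- as.integer(Mn)
  if (Mn < 1) abort("`Mn` must be >= 1.")
  round(exp(lfactorial(Mn) - lfactorial(Mn - 1L)))
}

parse_bits <- function(bits, n) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L, nchar(bits) == n)
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  bits <- as.integer(bits)
  if (length(bits) != n || any(!bits %in% c(0L, 1L))) {
    abort(sprintf("Expected %d bits in {0,1}.", n))
  }
  bits
}
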