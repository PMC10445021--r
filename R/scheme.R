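#' Kinetic gating schemes
#'
#' A gating scheme is a linear chain of conformational states, each carrying
#' a conductance weight (0 for closed, 1 for open) and a residence-time law
#' governing how long the channel stays there before the next transition.
#'
#' Topologies:
#' \describe{
#'   \item{`two_state`}{states `C`, `O`; the process alternates
#'     C -> O -> C -> ...}
#'   \item{`three_state_linear`}{states `C1`, `C2`, `O` on the chain
#'     C1 <-> C2 <-> O.  From `C1` the process moves to `C2`; from `C2`
#'     it branches to `O` with probability `p_c2_open` and back to `C1`
#'     otherwise (the competing-risks semi-Markov construction, with the
#'     dwell drawn from C2's law and the branch probability equal to
#'     \eqn{k_{C2\to O}/(k_{C2\to O}+k_{C2\to C1})}).  After an open
#'     sojourn the process re-enters the closed side at `C2`
#'     (`o_reentry = "C2"`, the strict linear chain) or at `C1`
#'     (`o_reentry = "C1"`, the renewal cycle
#'     Closed1 -> Closed2 -> Open -> Closed1 in which every closing
#'     restarts the closed relaxation from the first closed stage).}
#' }
#'
#' @param topology `"two_state"` or `"three_state_linear"`.
#' @param dwell_laws named list of [dwell_law()] objects, one per state:
#'   names `C`, `O` for two-state; `C1`, `C2`, `O` for three-state.
#' @param p_c2_open branch probability from `C2` to `O` (three-state only).
#' @param o_reentry closed state entered after an open sojourn
#'   (three-state only): `"C2"` (default) or `"C1"`.
#' @return An object of class `gating_scheme` with elements `topology`,
#'   `states` (data frame of labels and conductance weights), `dwell_laws`
#'   and, for the three-state chain, `p_c2_open`.
#' @examples
#' two_state_scheme(dwell_law("exponential", rate = 2),
#'                  dwell_law("exponential", rate = 1))
#' @export
gating_scheme <- function(topology = c("two_state", "three_state_linear"),
                          dwell_laws, p_c2_open = 0.5,
                          o_reentry = c("C2", "C1")) {
  topology <- match.arg(topology)
  o_reentry <- match.arg(o_reentry)
  wanted <- if (topology == "two_state") c("C", "O") else c("C1", "C2", "O")
  if (!is.list(dwell_laws) || !setequal(names(dwell_laws), wanted))
    stop("dwell_laws must be a named list with one law per state: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  if (!all(vapply(dwell_laws, inherits, logical(1), "dwell_law")))
    stop("every element of dwell_laws must be a dwell_law", call. = FALSE)
  if (topology == "three_state_linear") {
    stopifnot(is.numeric(p_c2_open), p_c2_open > 0, p_c2_open <= 1)
  }
  states <- data.frame(
    label = wanted,
    conductance_weight = as.numeric(wanted == "O"),
    stringsAsFactors = FALSE
  )
  out <- list(topology = topology, states = states,
              dwell_laws = dwell_laws[wanted])
  if (topology == "three_state_linear") {
    out$p_c2_open <- p_c2_open
    out$o_reentry <- o_reentry
  }
  structure(out, class = "gating_scheme")
}

#' @rdname gating_scheme
#' @param closed,open dwell laws for the closed and open state.
#' @export
two_state_scheme <- function(closed, open) {
  gating_scheme("two_state", list(C = closed, O = open))
}

#' @rdname gating_scheme
#' @param c1,c2 dwell laws for the two closed states.
#' @export
three_state_scheme <- function(c1, c2, open, p_c2_open = 0.5,
                               o_reentry = c("C2", "C1")) {
  gating_scheme("three_state_linear", list(C1 = c1, C2 = c2, O = open),
                p_c2_open = p_c2_open, o_reentry = o_reentry)
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("<gating_scheme>", x$topology, "\n")
  for (lab in x$states$label) {
    cat(" ", lab, "(g =", x$states$conductance_weight[x$states$label == lab],
        "): ")
    print(x$dwell_laws[[lab]])
  }
  if (!is.null(x$p_c2_open))
    cat("  branch P(C2 -> O) =", x$p_c2_open, "\n")
  invisible(x)
}

# next state given the current one; branching decided by `u` in (0,1)
.next_state <- function(scheme, state, u = NULL) {
  if (scheme$topology == "two_state") {
    return(if (state == "C") "O" else "C")
  }
  switch(state,
    C1 = "C2",
    O  = scheme$o_reentry,
    C2 = if (u < scheme$p_c2_open) "O" else "C1",
    stop("unknown state: ", state, call. = FALSE))
}
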