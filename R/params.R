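#' Rate constants of the Notch-Wnt-YAP activity network
#'
#' Constructs the parameter set of the four-variable regulatory network that
#' couples Notch activity in a transit amplifying cell (TAC), Wnt activity in
#' the interacting epidermal stem cell (SC), Wnt activity in the TAC, and
#' nuclear YAP activity in the TAC. Each activity obeys
#' d(A)/dt = regulation - degradation + generation, where the regulation term
#' is a Hill function of the other activities, the degradation term is
#' first-order, and the generation term is a constant basal production.
#'
#' Defaults are the baseline set used throughout the oscillatory analyses
#' (kNotch = 1, kWntSC = 1.4, kWntTA = 1, kYAP = 0.188, all TAC/SC degradation
#' constants 0.2 except kdYAP = 0.02, basal productions 0.1 except
#' kPNotch = 0.05, Hill coefficient n = 2).
#'
#' @param kNotch,kWntSC,kWntTA,kYAP Maximal Hill-regulation rates (a.u./time),
#'   must be >= 0.
#' @param kdNotch,kdWntSC,kdWntTA,kdYAP First-order degradation rate constants
#'   (1/time), must be > 0 so that long-term dynamics are bounded.
#' @param kPNotch,kPWntSC,kPWntTA,kPYAP Constant generation rates (a.u./time),
#'   must be >= 0.
#' @param n Hill coefficient (cooperativity), >= 1. Integer values are the
#'   biologically motivated case (default 2); non-integer values are accepted
#'   numerically but flagged with a message.
#' @param ... Ignored; present so that presets can splice in extra list fields.
#' @return An object of class `network_params`: a named list of the 13
#'   parameters.
#' @seealso [network_rhs()], [integrate_network()], [scenario_preset()]
#' @examples
#' p <- network_params()            # oscillatory baseline
#' p2 <- network_params(kPNotch = 0.2)  # monostable variant
#' @export
network_params <- function(kNotch = 1, kWntSC = 1.4, kWntTA = 1, kYAP = 0.188,
                           kdNotch = 0.2, kdWntSC = 0.2, kdWntTA = 0.2,
                           kdYAP = 0.02,
                           kPNotch = 0.05, kPWntSC = 0.1, kPWntTA = 0.1,
                           kPYAP = 0.1, n = 2, ...) {
  p <- list(kNotch = kNotch, kWntSC = kWntSC, kWntTA = kWntTA, kYAP = kYAP,
            kdNotch = kdNotch, kdWntSC = kdWntSC, kdWntTA = kdWntTA,
            kdYAP = kdYAP,
            kPNotch = kPNotch, kPWntSC = kPWntSC, kPWntTA = kPWntTA,
            kPYAP = kPYAP, n = n)
  validate_network_params(p)
  if (abs(n - round(n)) > .Machine$double.eps^0.5)
    message("non-integer Hill coefficient n = ", n,
            " accepted; integer n is the biologically motivated case")
  structure(p, class = "network_params")
}

#' @rdname network_params
#' @export
rate_symbols <- function() {
  c("kNotch", "kWntSC", "kWntTA", "kYAP",
    "kdNotch", "kdWntSC", "kdWntTA", "kdYAP",
    "kPNotch", "kPWntSC", "kPWntTA", "kPYAP")
}

param_names <- function() c(rate_symbols(), "n")

validate_network_params <- function(p) {
  miss <- setdiff(param_names(), names(p))
  if (length(miss))
    stop("missing network parameter(s): ", paste(miss, collapse = ", "))
  for (nm in param_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  rates <- c("kNotch", "kWntSC", "kWntTA", "kYAP",
             "kPNotch", "kPWntSC", "kPWntTA", "kPYAP")
  for (nm in rates)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0")
  for (nm in c("kdNotch", "kdWntSC", "kdWntTA", "kdYAP"))
    if (p[[nm]] <= 0) stop("degradation constant '", nm, "' must be > 0")
  if (p$n < 1) stop("Hill coefficient 'n' must be >= 1")
  invisible(p)
}

#' Modify a network parameter set
#'
#' Returns a new validated `network_params` with the named fields replaced.
#'
#' @param params A [network_params()] object.
#' @param ... Named replacements, e.g. `kPNotch = 0.06`.
#' @return A `network_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  bad <- setdiff(names(repl), param_names())
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_network_params(p)
  structure(p, class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("Notch-Wnt-YAP network parameters (a.u.)\n")
  v <- unlist(unclass(x))
  cat("  regulation :", paste(sprintf("%s=%g", names(v)[1:4], v[1:4]),
                              collapse = "  "), "\n")
  cat("  degradation:", paste(sprintf("%s=%g", names(v)[5:8], v[5:8]),
                              collapse = "  "), "\n")
  cat("  generation :", paste(sprintf("%s=%g", names(v)[9:12], v[9:12]),
                              collapse = "  "), "\n")
  cat("  Hill coefficient n =", x$n, "\n")
  invisible(x)
}

#' @export
as.list.network_params <- function(x, ...) unclass(x)

#' @export
coef.network_params <- function(object, ...) unlist(unclass(object))

#' Normalized pathway activity state
#'
#' The state vector of the network: Notch activity in the TAC, Wnt activity in
#' the SC, Wnt activity in the TAC, and nuclear YAP activity in the TAC. All
#' activities are dimensionless (normalized by the Hill half-saturation
#' constant K, which therefore never appears as a separate parameter) and must
#' be non-negative.
#'
#' @param A_Notch,A_WntSC,A_WntTA,A_YAP Non-negative scalar activities (a.u.).
#' @return A named numeric vector of length 4 with class `activity_state`.
#' @export
activity_state <- function(A_Notch = 0.1, A_WntSC = 0.1, A_WntTA = 0.1,
                           A_YAP = 0.1) {
  s <- c(A_Notch = A_Notch, A_WntSC = A_WntSC, A_WntTA = A_WntTA,
         A_YAP = A_YAP)
  validate_state(s)
  structure(s, class = "activity_state")
}

state_names <- function() c("A_Notch", "A_WntSC", "A_WntTA", "A_YAP")

validate_state <- function(s) {
  if (length(s) != 4L || !is.numeric(s))
    stop("an activity state must be a numeric vector of length 4")
  if (any(!is.finite(s))) stop("activity state must be finite")
  if (any(s < 0)) stop("activity state components must be >= 0")
  invisible(s)
}

as_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 4L) stop("state must have 4 components")
  names(s) <- state_names()
  s
}

#' Read or write a network parameter configuration
#'
#' Parameter sets are serialized to a flat key-value mapping (YAML or JSON by
#' file extension) whose keys are exactly the model symbols
#' (`kNotch`, ..., `kPYAP`, `n`). Unknown keys are rejected on read.
#'
#' @param params A [network_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params()` returns a `network_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: ", path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path)) read_yaml_config(path)
       else if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
       else stop("unsupported config extension: ", path)
  as_network_params(x)
}

# YAML 1.1 resolves a bare `n` (the Hill coefficient key) as boolean; the
# handlers restore the literal key spelling used by the config schema
read_yaml_config <- function(path) {
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) "y", "bool#no" = function(x) "n"))
}

#' @rdname write_params
#' @param x A named list of parameter values (possibly partial; unset
#'   parameters take their baseline defaults).
#' @export
as_network_params <- function(x) {
  if (inherits(x, "network_params")) return(x)
  if (is.null(x) || length(x) == 0L) return(network_params())
  bad <- setdiff(names(x), param_names())
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  do.call(network_params, x)
}
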