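## Equilibrium continuation, Hopf/fold detection, oscillatory-range scans.

# Newton iteration on the network RHS with the analytic Jacobian
newton_equilibrium <- function(x0, params, tol = 1e-12, maxit = 60L) {
  x <- as.numeric(x0)
  for (i in seq_len(maxit)) {
    f <- network_rhs(x, params)
    if (max(abs(f)) < tol) return(list(x = x, converged = TRUE))
    J <- network_jacobian(x, params)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(J + diag(1e-10, 4L), f)  # regularize near folds
    }
    x <- x - step
    if (any(!is.finite(x))) return(list(x = x0, converged = FALSE))
  }
  list(x = x, converged = max(abs(network_rhs(x, params))) < 1e-9)
}

#' Locate all equilibria of the network by multistart root-finding
#'
#' Newton iterations started from a Latin-hypercube sample of the
#' forward-invariant box (component-wise `[kP/kd, (k + kP)/kd]`, slightly
#' inflated), deduplicated, and verified to satisfy `max |rhs| < 1e-10`.
#' Multiple equilibria coexist in the bistable regime, hence the multistart.
#'
#' @param params A [network_params()] object.
#' @param n_starts Number of quasi-random starts (default 64).
#' @param seed RNG seed for the start sample (default 1).
#' @return A list of equilibria, each a list with `state` (named numeric),
#'   `eigenvalues` (complex, length 4) and `stable` (logical), ordered by
#'   increasing Notch activity.
#' @export
find_equilibria <- function(params, n_starts = 64L, seed = 1L) {
  stopifnot(n_starts >= 1L)
  box <- bounding_box(params)
  lo <- pmax(0, box$lower * 0.5)
  hi <- box$upper * 1.1
  u <- withr_seed(seed, lhs::randomLHS(n_starts, 4L))
  starts <- sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_equilibrium(starts[i, ], params)
    if (!r$converged) next
    x <- pmax(r$x, 0)
    r2 <- newton_equilibrium(x, params)
    if (!r2$converged || any(r2$x < -1e-9)) next
    if (max(abs(network_rhs(r2$x, params))) >= 1e-10) next
    dup <- any(vapply(roots, function(q)
      sqrt(sum((q - r2$x)^2)) < 1e-6, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r2$x
  }
  if (!length(roots)) stop("no equilibrium found; increase n_starts")
  roots <- roots[order(vapply(roots, `[`, numeric(1), 1L))]
  lapply(roots, function(x) {
    ev <- eigen(network_jacobian(x, params), only.values = TRUE)$values
    list(state = as_state(x), eigenvalues = ev, stable = max(Re(ev)) < 0)
  })
}

# run expr with a local RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# extended Jacobian [dF/dx | dF/dp] at u = (x, p)
extended_jacobian <- function(u, params, vary) {
  params[[vary]] <- u[5L]
  cbind(network_jacobian(u[1:4], params),
        param_gradient(u[1:4], params, vary))
}

extended_rhs <- function(u, params, vary) {
  params[[vary]] <- u[5L]
  network_rhs(u[1:4], params)
}

# corrector: Newton on (F(x,p), tangent . (u - u_pred)) = 0
arclength_correct <- function(u_pred, u_prev, tangent, ds, params, vary,
                              tol = 1e-11, maxit = 30L) {
  u <- u_pred
  for (i in seq_len(maxit)) {
    Fv <- c(extended_rhs(u, params, vary), sum(tangent * (u - u_prev)) - ds)
    if (max(abs(Fv)) < tol) return(list(u = u, converged = TRUE))
    Jf <- rbind(extended_jacobian(u, params, vary), tangent)
    step <- tryCatch(solve(Jf, Fv), error = function(e) NULL)
    if (is.null(step)) return(list(u = u, converged = FALSE))
    u <- u - step
    if (any(!is.finite(u))) return(list(u = u, converged = FALSE))
  }
  list(u = u, converged = FALSE)
}

# unit null vector of the 4x5 extended Jacobian (branch tangent)
branch_tangent <- function(u, params, vary) {
  Je <- extended_jacobian(u, params, vary)
  tn <- qr.Q(qr(t(Je)), complete = TRUE)[, 5L]
  tn / sqrt(sum(tn^2))
}

#' One-parameter equilibrium continuation with Hopf and fold detection
#'
#' Traces the equilibrium branch of the network as one rate constant varies
#' over a bracket, using pseudo-arclength predictor-corrector steps (the
#' analytic Jacobian supplies both the corrector and the branch tangent), so
#' folds are traversed rather than lost. Eigenvalues of the Jacobian are
#' recorded at every accepted point.
#'
#' A Hopf point is recorded where the leading eigenvalue real part crosses
#' zero with a nonzero imaginary part; a fold (limit point) where the branch
#' parameter passes a local extremum, i.e. a real eigenvalue crosses zero.
#' Both are refined by bisection along the branch to a parameter tolerance
#' of 1e-5.
#'
#' @param params A [network_params()] object (values of `vary` in it are
#'   ignored; the bracket's left end is the starting point).
#' @param vary One of the 12 rate-constant names.
#' @param bracket Length-2 numeric interval for the varied parameter.
#' @param ds Initial arclength step (adaptive: halved on corrector failure,
#'   grown on easy steps).
#' @param max_steps Safety cap on accepted continuation points.
#' @param x0 Optional starting equilibrium; defaults to the one found by
#'   [find_equilibria()] at the bracket's left end.
#' @param seed Seed forwarded to [find_equilibria()] for the multistart.
#' @return An object of class `bifurcation_branch`: a data.frame with the
#'   parameter value, the four state components, eigenvalue real and
#'   imaginary parts (`re1..re4`, `im1..im4`, ordered by decreasing real
#'   part) and a `stable` flag, with `hopf_points` and `fold_points`
#'   data.frames as attributes.
#' @export
continue_equilibria <- function(params, vary, bracket, ds = 0.02,
                                max_steps = 5000L, x0 = NULL, seed = 1L) {
  stopifnot(length(bracket) == 2L, all(is.finite(bracket)))
  from <- bracket[1L]; to <- bracket[2L]
  if (!vary %in% rate_symbols()) stop("cannot continue in '", vary, "'")
  p <- params
  p[[vary]] <- from
  if (is.null(x0)) {
    eqs <- find_equilibria(p, seed = seed)
    x0 <- as.numeric(eqs[[1L]]$state)
  } else {
    x0 <- newton_equilibrium(x0, p)$x
  }
  u <- c(x0, from)
  tangent <- branch_tangent(u, params, vary)
  if ((to - from) * tangent[5L] < 0) tangent <- -tangent

  pts <- vector("list", max_steps)
  add_point <- function(u) {
    pp <- params; pp[[vary]] <- u[5L]
    ev <- eigen(network_jacobian(u[1:4], pp), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    list(u = u, ev = ev)
  }
  pts[[1L]] <- add_point(u)
  npts <- 1L
  truncated <- FALSE
  ds_now <- ds
  lo <- min(from, to); hi <- max(from, to)
  while (npts < max_steps) {
    pred <- u + ds_now * tangent
    corr <- arclength_correct(pred, u, tangent, ds_now, params, vary)
    if (!corr$converged) {
      ds_now <- ds_now / 2
      if (ds_now < ds * 1e-4) { truncated <- TRUE; break }
      next
    }
    u_new <- corr$u
    tn <- branch_tangent(u_new, params, vary)
    if (sum(tn * tangent) < 0) tn <- -tn
    npts <- npts + 1L
    pts[[npts]] <- add_point(u_new)
    u <- u_new; tangent <- tn
    ds_now <- min(ds, ds_now * 1.3)
    if (u[5L] > hi + ds || u[5L] < lo - ds) break
  }
  pts <- pts[seq_len(npts)]

  param_values <- vapply(pts, function(q) q$u[5L], numeric(1))
  states <- t(vapply(pts, function(q) q$u[1:4], numeric(4)))
  evs <- t(vapply(pts, function(q) q$ev, complex(4)))
  df <- data.frame(param = param_values, states,
                   Re(evs), Im(evs),
                   stable = apply(Re(evs), 1L, max) < 0)
  names(df) <- c("param", state_names(),
                 paste0("re", 1:4), paste0("im", 1:4), "stable")

  special <- locate_special_points(pts, params, vary)
  structure(df, class = c("bifurcation_branch", "data.frame"),
            vary = vary, bracket = sort(c(from, to)),
            hopf_points = special$hopf, fold_points = special$fold,
            truncated = truncated, params = params)
}

# detect + refine Hopf (leading real-part zero crossing, complex pair) and
# fold (parameter extremum along the branch) points
locate_special_points <- function(pts, params, vary) {
  n <- length(pts)
  maxre <- vapply(pts, function(q) max(Re(q$ev)), numeric(1))
  pv <- vapply(pts, function(q) q$u[5L], numeric(1))
  hopf <- list(); fold <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (is.na(maxre[i]) || is.na(maxre[i + 1L])) next
      if (maxre[i] == 0 || maxre[i] * maxre[i + 1L] < 0) {
        ref <- refine_crossing(pts[[i]]$u, pts[[i + 1L]]$u, params, vary,
                               test = leading_re)
        if (!is.null(ref)) {
          if (ref$is_complex) hopf[[length(hopf) + 1L]] <- ref
          else fold[[length(fold) + 1L]] <- ref
        }
      }
    }
  }
  if (n >= 3L) {
    dp <- diff(pv)
    for (i in seq_len(n - 2L)) {
      if (dp[i] * dp[i + 1L] < 0) {
        ref <- refine_crossing(pts[[i]]$u, pts[[i + 2L]]$u, params, vary,
                               test = critical_real)
        if (!is.null(ref)) fold[[length(fold) + 1L]] <- ref
      }
    }
  }
  list(hopf = special_df(hopf), fold = special_df(dedupe_special(fold)))
}

# test functions: value whose zero is sought, along the branch
leading_re <- function(ev) max(Re(ev))
critical_real <- function(ev) {
  re_real <- Re(ev[abs(Im(ev)) < 1e-8])
  if (!length(re_real)) return(NA_real_)
  re_real[which.min(abs(re_real))]
}

# bisection in arclength between two branch points; Newton-corrects the
# midpoint onto the branch at each step, to parameter tolerance 1e-5
refine_crossing <- function(ua, ub, params, vary, test, tol = 1e-5,
                            maxit = 60L) {
  fa <- test(point_eigen(ua, params, vary))
  fb <- test(point_eigen(ub, params, vary))
  if (is.na(fa) || is.na(fb)) return(NULL)
  if (fa == 0) return(special_entry(ua, params, vary))
  if (fa * fb > 0) return(NULL)
  for (i in seq_len(maxit)) {
    um <- (ua + ub) / 2
    tang <- (ub - ua); tang <- tang / sqrt(sum(tang^2))
    corr <- arclength_correct(um, ua, tang, sqrt(sum((um - ua)^2)),
                              params, vary)
    if (!corr$converged) return(NULL)
    um <- corr$u
    fm <- test(point_eigen(um, params, vary))
    if (is.na(fm)) return(NULL)
    if (fa * fm <= 0) ub <- um else { ua <- um; fa <- fm }
    # folds are parameter extrema, so the state distance must shrink too
    if (abs(ub[5L] - ua[5L]) < tol &&
        sqrt(sum((ub - ua)^2)) < 1e-6) break
  }
  special_entry((ua + ub) / 2, params, vary)
}

point_eigen <- function(u, params, vary) {
  params[[vary]] <- u[5L]
  eigen(network_jacobian(u[1:4], params), only.values = TRUE)$values
}

special_entry <- function(u, params, vary) {
  ev <- point_eigen(u, params, vary)
  lead <- ev[which.max(Re(ev))]
  list(param = u[5L], state = as_state(u[1:4]),
       is_complex = abs(Im(lead)) > 1e-6,
       eigenvalue = lead)
}

dedupe_special <- function(lst, tol = 1e-4) {
  out <- list()
  for (e in lst) {
    dup <- any(vapply(out, function(q) abs(q$param - e$param) < tol,
                      logical(1)))
    if (!dup) out[[length(out) + 1L]] <- e
  }
  out
}

special_df <- function(lst) {
  if (!length(lst))
    return(data.frame(param = numeric(), A_Notch = numeric(),
                      A_WntSC = numeric(), A_WntTA = numeric(),
                      A_YAP = numeric()))
  df <- do.call(rbind, lapply(lst, function(e)
    data.frame(param = e$param, t(e$state))))
  df[order(df$param), , drop = FALSE]
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat(sprintf("Equilibrium branch in '%s' over [%g, %g]: %d points\n",
              attr(x, "vary"), attr(x, "bracket")[1L],
              attr(x, "bracket")[2L], nrow(x)))
  hp <- attr(x, "hopf_points"); fp <- attr(x, "fold_points")
  if (nrow(hp)) cat("  Hopf points at:",
                    paste(format(hp$param, digits = 6), collapse = ", "), "\n")
  if (nrow(fp)) cat("  fold points at:",
                    paste(format(fp$param, digits = 6), collapse = ", "), "\n")
  if (!nrow(hp) && !nrow(fp)) cat("  no special points detected\n")
  if (isTRUE(attr(x, "truncated")))
    cat("  warning: branch truncated before leaving the bracket\n")
  invisible(x)
}

#' @export
summary.bifurcation_branch <- function(object, ...) {
  print(object)
  cat(sprintf("  stable points: %d / %d\n", sum(object$stable), nrow(object)))
  invisible(object)
}

#' @export
plot.bifurcation_branch <- function(x, var = "A_Notch", ...) {
  graphics::plot(x$param, x[[var]], type = "n",
                 xlab = attr(x, "vary"), ylab = var, ...)
  graphics::points(x$param[x$stable], x[[var]][x$stable], pch = 16, cex = 0.4)
  graphics::points(x$param[!x$stable], x[[var]][!x$stable], pch = 1,
                   cex = 0.4, col = "grey50")
  hp <- attr(x, "hopf_points")
  if (nrow(hp)) graphics::points(hp$param, hp[[var]], pch = 17, col = "red")
  fp <- attr(x, "fold_points")
  if (nrow(fp)) graphics::points(fp$param, fp[[var]], pch = 15, col = "blue")
  invisible(x)
}

#' Hopf points of a branch
#' @param branch A `bifurcation_branch`.
#' @return A data.frame of Hopf (or fold) parameter values and equilibria.
#' @export
hopf_points <- function(branch) attr(branch, "hopf_points")

#' @rdname hopf_points
#' @export
fold_points <- function(branch) attr(branch, "fold_points")

#' Write a bifurcation branch to CSV (with special points as JSON)
#'
#' @param branch A `bifurcation_branch`.
#' @param path Output CSV path; special points go to `<path>.special.json`.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  write_tidy_csv(as.data.frame(branch), path)
  sp <- list(vary = attr(branch, "vary"),
             hopf_points = attr(branch, "hopf_points"),
             fold_points = attr(branch, "fold_points"))
  jsonlite::write_json(sp, paste0(path, ".special.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
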