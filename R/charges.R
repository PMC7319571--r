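# User-facing front door: one function dispatching to the ten charge
# methods, plus the methods of the charge_result class.

#' Calculate partial atomic charges
#'
#' Runs one empirical charge method on a molecule.  With
#' \code{method = "auto"} the method and parameter set are chosen
#' automatically (see \code{\link{select_automatic}}); explicit choices
#' override.  Large equalization systems are routed to the cutoff/cover
#' approximations by atom count unless a strategy is forced.
#'
#' @param mol a \code{molecule}, or a path accepted by
#'   \code{\link{read_structures}} (first molecule is used).
#' @param method method id (\code{"eem"}, \code{"qeq"}, \code{"peoe"},
#'   ...) or \code{"auto"}.
#' @param parameters a \code{parameter_set}, a parameter-set id from the
#'   registry, a JSON file path, or \code{"auto"}.
#' @param strategy \code{"auto"}, \code{"full"}, \code{"cutoff"} or
#'   \code{"cover"} (equalization methods only).
#' @param radius cutoff/cover subsystem radius in Angstrom.
#' @param registry parameter registry used for lookups.
#' @param ... further arguments passed to the method function (e.g.
#'   \code{tol}, \code{max_iter} for the iterative schemes).
#' @return a \code{charge_result}: per-atom charges plus provenance
#'   (method, parameter set, solver strategy).
#' @export
#' @examples
#' mol <- make_fixture("methane")
#' ps <- make_toy_parameters("eem", c("C", "H"))
#' calculate_charges(mol, method = "eem", parameters = ps)
calculate_charges <- function(mol, method = "auto", parameters = "auto",
                              strategy = "auto", radius = 12,
                              registry = parameter_registry(), ...) {
  if (is.character(mol)) {
    rd <- read_structures(mol)
    if (!rd$report$ok) stop("input failed validation; inspect read_structures()")
    mol <- rd$molecules[[1]]
  }
  stopifnot(inherits(mol, "molecule"))
  ps <- NULL
  if (identical(method, "auto")) {
    sel <- select_automatic(list(mol), registry)
    method <- sel$method$id
    ps <- sel$parameters
  }
  desc <- method_descriptor(method)
  if (desc$needs_parameters && is.null(ps)) {
    ps <- resolve_parameters(parameters, desc, mol, registry)
  }
  dispatch_method(mol, desc, ps, strategy, radius, ...)
}

resolve_parameters <- function(parameters, desc, mol, registry) {
  if (inherits(parameters, "parameter_set")) {
    ps <- parameters
  } else if (identical(parameters, "auto")) {
    sets <- Filter(function(p) p$method == desc$id, registry)
    cov <- Filter(function(p) applicability(p, mol)$ok, sets)
    if (!length(cov)) {
      stop("no bundled parameter set of method '", desc$id,
           "' covers molecule '", mol$name, "'")
    }
    surplus <- vapply(cov, function(p) {
      length(p$atom) - length(unique(classify_atom(mol, scheme = p$scheme)))
    }, numeric(1))
    ps <- cov[[which.min(surplus)]]
  } else if (is.character(parameters) && file.exists(parameters)) {
    ps <- load_parameter_set(parameters)
  } else if (is.character(parameters) && parameters %in% names(registry)) {
    ps <- registry[[parameters]]
  } else {
    stop("cannot resolve parameter set: ", parameters)
  }
  if (ps$method != desc$id) {
    stop("parameter set '", ps$id, "' belongs to method '", ps$method,
         "', not '", desc$id, "'")
  }
  app <- applicability(ps, mol)
  if (!app$ok) {
    stop("parameter set '", ps$id, "' does not cover molecule '", mol$name,
         "'; missing type(s): ", paste(app$missing, collapse = ", "))
  }
  ps
}

dispatch_method <- function(mol, desc, ps, strategy, radius, ...) {
  switch(desc$id,
    eem = eem_charges(mol, ps, strategy, radius),
    sfkeem = sfkeem_charges(mol, ps, strategy, radius),
    qeq = qeq_charges(mol, ps, strategy, radius, ...),
    eqeq = eqeq_charges(mol, ps, strategy, radius),
    eqeqc = eqeqc_charges(mol, ps, strategy, radius),
    gdac = gdac_charges(mol, ps, ...),
    peoe = peoe_charges(mol, ps, ...),
    mgc = mgc_charges(mol, ...),
    veem = veem_charges(mol),
    delre = delre_charges(mol, ps))
}

# charge_result methods ----------------------------------------------------

#' @export
print.charge_result <- function(x, ...) {
  cat(sprintf("<charge_result '%s': %s%s, %d atoms, strategy %s>\n",
              x$molecule, x$method,
              if (x$parameter_set != "none") paste0("/", x$parameter_set) else "",
              x$n_atoms, x$strategy))
  q <- x$charges
  shown <- utils::head(q, 8)
  cat("  charges:", paste(sprintf("%.4f", shown), collapse = " "),
      if (length(q) > 8) "..." else "", "\n")
  cat(sprintf("  sum = %+.6f%s\n", sum(q),
              if (!is.na(x$chibar)) sprintf(", chibar = %.4f", x$chibar) else ""))
  if (!x$converged) cat("  WARNING: iteration did not converge\n")
  invisible(x)
}

#' @export
summary.charge_result <- function(object, ...) {
  q <- object$charges
  out <- list(result = object,
              stats = c(n = length(q), sum = sum(q), min = min(q),
                        max = max(q), mean = mean(q), sd = stats::sd(q)))
  class(out) <- "summary.charge_result"
  out
}

#' @export
print.summary.charge_result <- function(x, ...) {
  print(x$result)
  s <- x$stats
  cat(sprintf("  range [%.4f, %.4f], mean %.4f, sd %.4f\n",
              s["min"], s["max"], s["mean"], s["sd"]))
  invisible(x)
}

#' @export
coef.charge_result <- function(object, ...) object$charges

#' Bar plot of per-atom charges
#'
#' @param x a \code{charge_result}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.charge_result <- function(x, ...) {
  q <- x$charges
  graphics::barplot(q, col = ifelse(q >= 0, "#3b6fb6", "#c23b22"),
                    border = NA, las = 2, cex.names = 0.6,
                    ylab = "partial charge (e)",
                    main = sprintf("%s: %s", x$molecule, x$method), ...)
  graphics::abline(h = 0)
  invisible(x)
}
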