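# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @method tidy permanova
#' @rdname permanova
#' @param x A `"permanova"` object.
#' @param ... Unused.
tidy.permanova <- function(x, ...) {
  tibble(term = "groups", pseudo_f = x$pseudo_f, r_squared = x$r_squared,
         p.value = x$p)
}

#' @export
#' @method glance permanova
#' @rdname permanova
glance.permanova <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, r_squared = x$r_squared, p.value = x$p,
         permutations = x$permutations, n_groups = x$n_groups, n = x$n)
}

#' @export
#' @method tidy permdisp
#' @rdname permdisp
#' @param x A `"permdisp"` object.
#' @param ... Unused.
tidy.permdisp <- function(x, ...) {
  rename(x$dispersion, term = "group")
}

#' @export
#' @method glance permdisp
#' @rdname permdisp
glance.permdisp <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p, degenerate = x$degenerate)
}

#' @export
#' @method tidy da_fit
#' @rdname bias_corrected_da
#' @param x A `"da_fit"` object.
#' @param ... Unused.
tidy.da_fit <- function(x, ...) {
  rename(x$results, estimate = "logfc", std.error = "se",
         conf.low = "ci_lo", conf.high = "ci_hi", p.value = "p")
}

#' @export
#' @method glance da_fit
#' @rdname bias_corrected_da
glance.da_fit <- function(x, ...) {
  tibble(n_genera = nrow(x$global),
         n_contrasts = length(unique(x$results$contrast)),
         n_significant = sum(x$results$significant, na.rm = TRUE),
         q_threshold = x$q_threshold)
}

#' @export
#' @method tidy roc_result
#' @rdname roc_curve
#' @param x A `"roc_result"` object.
#' @param ... Unused.
tidy.roc_result <- function(x, ...) x$points

#' @export
#' @method glance roc_result
#' @rdname roc_curve
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, positive = x$positive, direction = x$direction)
}

#' @export
#' @method tidy cooccurrence_network
#' @rdname build_network
#' @param x A `"cooccurrence_network"` object.
#' @param ... Unused.
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @export
#' @method glance cooccurrence_network
#' @rdname build_network
glance.cooccurrence_network <- function(x, ...) {
  tibble(group = x$group, n_nodes = x$n_nodes, n_edges = x$n_edges,
         density = x$density, components = x$components)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations, %d samples, %d groups)\n",
              x$pseudo_f, x$r_squared, x$p, x$permutations, x$n, x$n_groups))
  invisible(x)
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.3f, p = %.4g\n", x$f, x$p))
  print(x$dispersion)
  invisible(x)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network [%s]: %d nodes, %d edges, density %.4f, %d components\n",
              x$group, x$n_nodes, x$n_edges, x$density, x$components))
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (positive = %s, %s values positive): AUC = %.3f\n",
              x$positive, x$direction, x$auc))
  invisible(x)
}
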