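#' Two-sided Mann-Whitney U test
#'
#' The U statistic counts pairs with `x_i > y_j`, ties counted half
#' (computed via mid-ranks). For small samples (`min(n, m) <= 8`) without
#' ties the two-sided p-value comes from the exact U distribution;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used. Non-finite values are removed first.
#'
#' @param x,y numeric samples (non-empty after missing-value removal).
#' @return List with `U`, `p` (two-sided), sample sizes and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stopf("empty sample after missing-value removal")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (min(n, m) <= 8 && !ties) {
    p <- if (U > n * m / 2) {
      2 * stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n, m)
    }
    method <- "exact"
  } else {
    N <- n + m
    tt <- table(r)
    tie_term <- sum(tt^3 - tt)
    sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (max(abs(U - n * m / 2) - 0.5, 0)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-z)
    }
    method <- "normal_tie_corrected"
  }
  list(U = U, p = min(p, 1), n = n, m = m, method = method)
}

#' Feature-wise prototyping of neoplastic entities against the reactive baseline
#'
#' Stage 1 of the analysis: every profile feature of every neoplastic
#' entity is compared against the reactive (`reactive_label`) profiles
#' with the two-sided Mann-Whitney U test. A feature is coded `+1`
#' (increased) or `-1` (decreased) by the sign of the median difference
#' when `p < alpha`, else `0`. All images enter (no per-case
#' downscaling); p-values are unadjusted by default, matching the
#' `p < 0.05` criterion of the original analysis (Benjamini-Hochberg is
#' available behind `p_adjust = "BH"`). Multiple images of one case are
#' treated as independent observations — mirroring the source analysis —
#' and this is flagged in the result's `notes`.
#'
#' @param profiles profile tibble ([profile_columns()] layout).
#' @param reactive_label baseline diagnosis label (default `"LA"`).
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param features features to test (default: full registry).
#' @return Object of class `prototype_matrix`: long `table` tibble
#'   (entity, feature, U, p, medians, direction), `alpha`,
#'   `reactive_label`, `notes`.
#' @export
prototype_all <- function(profiles, reactive_label = "LA", alpha = 0.05,
                          p_adjust = c("none", "BH"),
                          features = feature_registry()) {
  p_adjust <- match.arg(p_adjust)
  if (!reactive_label %in% profiles$diagnosis) {
    stopf("unknown reactive label '%s': not present in profiles", reactive_label)
  }
  entities <- setdiff(unique(profiles$diagnosis), reactive_label)
  if (!length(entities)) stopf("no neoplastic entities besides '%s'", reactive_label)
  n_reactive <- sum(profiles$diagnosis == reactive_label)
  if (n_reactive < 3) stopf("need >= 3 reactive profiles, have %d", n_reactive)
  rows <- list()
  for (ent in entities) {
    n_ent <- sum(profiles$diagnosis == ent)
    if (n_ent < 3) stopf("need >= 3 profiles for entity '%s', have %d", ent, n_ent)
    for (f in features) {
      x <- profiles[[f]][profiles$diagnosis == ent]
      y <- profiles[[f]][profiles$diagnosis == reactive_label]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (!length(x) || !length(y)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          entity = ent, feature = f, U = NA_real_, p = NA_real_,
          median_entity = NA_real_, median_reactive = NA_real_,
          direction = NA_integer_, note = "skipped: no complete observations")
        next
      }
      test <- mann_whitney_u(x, y)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        entity = ent, feature = f, U = test$U, p = test$p,
        median_entity = stats::median(x), median_reactive = stats::median(y),
        direction = NA_integer_, note = NA_character_)
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (p_adjust == "BH") {
    ok <- !is.na(tab$p)
    tab$p[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  }
  tab$direction <- ifelse(is.na(tab$p), NA_integer_,
                          ifelse(tab$p < alpha,
                                 sign(tab$median_entity - tab$median_reactive), 0L))
  structure(list(table = tab, alpha = alpha, reactive_label = reactive_label,
                 p_adjust = p_adjust,
                 notes = paste("within-case image correlation is not modelled:",
                               "multiple images per case enter as independent samples")),
            class = "prototype_matrix")
}

#' Extract the prototype grid as an entity x feature matrix
#' @param x a `prototype_matrix`.
#' @param what `"direction"`, `"p"`, or `"U"`.
#' @param ... unused.
#' @return Numeric matrix, rows = entities, columns = registry features.
#' @export
as.matrix.prototype_matrix <- function(x, what = c("direction", "p", "U"), ...) {
  what <- match.arg(what)
  tab <- x$table
  ents <- unique(tab$entity); feats <- unique(tab$feature)
  out <- matrix(NA_real_, length(ents), length(feats),
                dimnames = list(ents, feats))
  out[cbind(match(tab$entity, ents), match(tab$feature, feats))] <- tab[[what]]
  out
}

#' @export
print.prototype_matrix <- function(x, ...) {
  d <- as.matrix(x, "direction")
  cat(sprintf("<prototype_matrix> %d entities x %d features vs '%s' (alpha %.3g, %s)\n",
              nrow(d), ncol(d), x$reactive_label, x$alpha, x$p_adjust))
  cat(sprintf("significant cells: %d increased, %d decreased, %d unchanged\n",
              sum(d == 1, na.rm = TRUE), sum(d == -1, na.rm = TRUE),
              sum(d == 0, na.rm = TRUE)))
  invisible(x)
}

#' Write prototype outputs (direction grid + p-values) as CSV
#' @param pm a `prototype_matrix`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_prototype <- function(pm, dir) {
  stopifnot(inherits(pm, "prototype_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("prototype_directions.csv", "prototype_pvalues.csv"))
  utils::write.csv(as.data.frame(as.matrix(pm, "direction")), paths[1])
  utils::write.csv(as.data.frame(as.matrix(pm, "p")), paths[2])
  invisible(paths)
}

#' Colored-grid plot of a prototype matrix
#'
#' Red tiles: significantly increased; green: decreased; grey: unchanged.
#' Requires ggplot2.
#'
#' @param pm a `prototype_matrix`.
#' @return A ggplot object.
#' @export
plot_prototype <- function(pm) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_prototype requires ggplot2")
  }
  tab <- pm$table
  tab$state <- factor(c("decreased", "unchanged", "increased")[tab$direction + 2L],
                      levels = c("increased", "decreased", "unchanged"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$feature, y = .data$entity,
                                    fill = .data$state)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(increased = "#c23b22",
                                          decreased = "#2e8b57",
                                          unchanged = "grey80"),
                               na.value = "white") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
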