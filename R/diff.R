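# Differential proteoform statistics between treatment conditions, and
# site-level marginalization for comparison with bottom-up data.

#' Group reporter signals by proteoform and test between conditions
#'
#' Per proteoform, pools all normalized log2 reporter signals by treatment
#' condition across its eligible scans, reports the difference of condition
#' means as the log2 fold change, and tests it with a two-sided two-sample
#' t-test (Welch by default). Significance is flagged at raw p <
#' \code{alpha}; Benjamini-Hochberg q-values are reported as an extra column
#' but do not drive the flag.
#'
#' @param channel_log2 Long data frame with columns \code{proteoform_id},
#'   \code{condition}, \code{log2_signal} (as in a \code{proteoform_quant}
#'   fit's \code{channel_log2} component).
#' @param vehicle,treated Condition labels; defaults: \code{vehicle} is the
#'   first condition of the data (alphabetically if ambiguous),
#'   \code{treated} the other. log2fc = mean(treated) - mean(vehicle).
#' @param min_obs Minimum observations per condition for a proteoform to be
#'   tested (default 2); proteoforms below it are reported in
#'   \code{attr(, "not_tested")}.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Significance level for the flag (strict \code{p < alpha}).
#' @return Object of class \code{"proteoform_diff"}: a data frame with
#'   columns \code{proteoform_id}, \code{log2fc}, \code{p_value},
#'   \code{q_value}, \code{n_vehicle}, \code{n_treated}, \code{significant},
#'   ordered by proteoform id; attributes \code{not_tested} and
#'   \code{conditions}.
#' @export
group_and_test <- function(channel_log2, vehicle = NULL, treated = NULL,
                           min_obs = 2L, var_equal = FALSE, alpha = 0.05) {
  conds <- sort(unique(channel_log2$condition))
  if (length(conds) != 2L) {
    stop("differential testing needs exactly 2 conditions, found ",
         length(conds), call. = FALSE)
  }
  if (is.null(vehicle) && is.null(treated)) {
    vehicle <- conds[1]
    treated <- conds[2]
  } else if (is.null(vehicle)) {
    vehicle <- setdiff(conds, treated)[1]
  } else if (is.null(treated)) {
    treated <- setdiff(conds, vehicle)[1]
  }
  if (!all(c(vehicle, treated) %in% conds) || vehicle == treated) {
    stop("vehicle/treated must name the two conditions", call. = FALSE)
  }
  ids <- sort(unique(channel_log2$proteoform_id))
  rows <- vector("list", length(ids))
  not_tested <- character(0)
  for (i in seq_along(ids)) {
    d <- channel_log2[channel_log2$proteoform_id == ids[i], , drop = FALSE]
    xv <- d$log2_signal[d$condition == vehicle]
    xt <- d$log2_signal[d$condition == treated]
    if (length(xv) < min_obs || length(xt) < min_obs) {
      not_tested <- c(not_tested, ids[i])
      next
    }
    p <- tryCatch(
      stats::t.test(xt, xv, var.equal = var_equal,
                    alternative = "two.sided")$p.value,
      error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      proteoform_id = ids[i], log2fc = mean(xt) - mean(xv), p_value = p,
      n_vehicle = length(xv), n_treated = length(xt),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(proteoform_id = character(0), log2fc = numeric(0),
                      p_value = numeric(0), n_vehicle = integer(0),
                      n_treated = integer(0), stringsAsFactors = FALSE)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[, c("proteoform_id", "log2fc", "p_value", "q_value",
                 "n_vehicle", "n_treated", "significant")]
  rownames(out) <- NULL
  structure(out, not_tested = not_tested,
            conditions = c(vehicle = vehicle, treated = treated),
            alpha = alpha, class = c("proteoform_diff", "data.frame"))
}

#' Differential proteoform analysis of a quantification fit
#'
#' Convenience wrapper applying \code{\link{group_and_test}} to the
#' normalized log2 reporter signals of a \code{\link{quantify_proteoforms}}
#' fit.
#'
#' @param object A \code{proteoform_quant} fit.
#' @param ... Passed to \code{\link{group_and_test}} (\code{vehicle},
#'   \code{treated}, \code{min_obs}, \code{var_equal}, \code{alpha}).
#' @return A \code{proteoform_diff} (see \code{\link{group_and_test}}).
#' @export
diff_proteoforms <- function(object, ...) {
  stopifnot(inherits(object, "proteoform_quant"))
  if (!nrow(object$channel_log2)) {
    stop("fit has no reporter-quantifiable scans", call. = FALSE)
  }
  args <- list(...)
  if (is.null(args$vehicle) && is.null(args$treated)) {
    # the design's first channel carries the reference (vehicle) condition
    args$vehicle <- object$design$conditions[[object$design$channels[1]]]
  }
  do.call(group_and_test, c(list(object$channel_log2), args))
}

#' @export
print.proteoform_diff <- function(x, ...) {
  cc <- attr(x, "conditions")
  cat(sprintf("Differential proteoform analysis: %s vs %s\n",
              cc[["treated"]], cc[["vehicle"]]))
  cat(sprintf(" %d proteoforms tested, %d significant (p < %g); %d quantified but not tested\n",
              nrow(x), sum(x$significant), attr(x, "alpha"),
              length(attr(x, "not_tested"))))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Volcano plot of differential proteoforms
#'
#' @param x A \code{proteoform_diff}.
#' @param label_sig Label significant points with their proteoform ids.
#' @param ... Passed to \code{plot}.
#' @export
plot.proteoform_diff <- function(x, label_sig = TRUE, ...) {
  if (!nrow(x)) {
    warning("nothing to plot")
    return(invisible(NULL))
  }
  y <- -log10(x$p_value)
  graphics::plot(x$log2fc, y, pch = 19,
                 col = ifelse(x$significant, "firebrick", "grey40"),
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ p),
                 main = "Differential proteoforms", ...)
  graphics::abline(h = -log10(attr(x, "alpha")), lty = 2, col = "grey60")
  graphics::abline(v = 0, lty = 3, col = "grey80")
  if (label_sig && any(x$significant)) {
    graphics::text(x$log2fc[x$significant], y[x$significant],
                   x$proteoform_id[x$significant], pos = 3, cex = 0.6)
  }
  invisible(x)
}

#' Plot-ready volcano table
#'
#' One row per tested proteoform with log2 fold change, -log10 p, mean
#' abundance and the significance flag, ordered by mean abundance descending
#' (ties by id).
#'
#' @param diff A \code{proteoform_diff}.
#' @param quant Optional \code{proteoform_quant} fit supplying the abundance
#'   column (NA otherwise).
#' @return Data frame with columns \code{proteoform_id}, \code{log2fc},
#'   \code{neg_log10_p}, \code{mean_abundance}, \code{significant}.
#' @export
volcano_table <- function(diff, quant = NULL) {
  d <- as.data.frame(diff)
  out <- data.frame(proteoform_id = d$proteoform_id, log2fc = d$log2fc,
                    neg_log10_p = -log10(d$p_value),
                    mean_abundance = rep(NA_real_, nrow(d)),
                    significant = d$significant, stringsAsFactors = FALSE)
  if (!is.null(quant)) {
    ab <- stats::setNames(quant$abundance$abundance,
                          quant$abundance$proteoform_id)
    out$mean_abundance <- unname(ab[out$proteoform_id])
  }
  out <- out[order(-ifelse(is.na(out$mean_abundance), -Inf, out$mean_abundance),
                   out$proteoform_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marginalize proteoform abundances to site-level PTM abundances
#'
#' The site-level abundance of a positioned modification (e.g. K9ac) is the
#' sum of the abundances of all proteoforms carrying it; the unmodified
#' fraction of a site is 1 minus the sum over all modifications at that site.
#'
#' @param x A \code{proteoform_quant} fit, or a data frame with columns
#'   \code{proteoform_id} and \code{abundance}.
#' @param proteoforms Named list of \code{proteoform} objects keyed by id
#'   (taken from the fit when \code{x} is one).
#' @param include_unmodified Also emit per-site unmodified fractions
#'   (labelled e.g. \code{K9un}).
#' @return Data frame with columns \code{label}, \code{position}, \code{mod},
#'   \code{abundance}, sorted by position then label.
#' @export
marginalize_sites <- function(x, proteoforms = NULL,
                              include_unmodified = FALSE) {
  if (inherits(x, "proteoform_quant")) {
    proteoforms <- x$proteoforms
    ab <- x$abundance
  } else ab <- x
  if (is.null(proteoforms)) stop("proteoform definitions required", call. = FALSE)
  acc <- list()
  for (i in seq_len(nrow(ab))) {
    p <- proteoforms[[ab$proteoform_id[i]]]
    if (is.null(p)) stop("no proteoform definition for ", ab$proteoform_id[i],
                         call. = FALSE)
    if (!nrow(p$mods)) next
    res <- strsplit(p$sequence, "")[[1]]
    lab <- paste0(res[p$mods$position], p$mods$position,
                  .mod_short[p$mods$name])
    for (k in seq_along(lab)) {
      key <- lab[k]
      if (is.null(acc[[key]])) {
        acc[[key]] <- list(position = p$mods$position[k],
                           mod = p$mods$name[k], abundance = 0)
      }
      acc[[key]]$abundance <- acc[[key]]$abundance + ab$abundance[i]
    }
  }
  if (!length(acc)) {
    return(data.frame(label = character(0), position = integer(0),
                      mod = character(0), abundance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    label = names(acc),
    position = vapply(acc, `[[`, numeric(1), "position"),
    mod = vapply(acc, `[[`, character(1), "mod"),
    abundance = vapply(acc, `[[`, numeric(1), "abundance"),
    stringsAsFactors = FALSE)
  if (include_unmodified) {
    site_tot <- tapply(out$abundance, out$position, sum)
    first <- out[!duplicated(out$position), , drop = FALSE]
    un <- data.frame(
      label = paste0(substr(first$label, 1, 1), first$position, "un"),
      position = first$position, mod = "unmodified",
      abundance = pmax(0, 1 - as.numeric(site_tot[as.character(first$position)])),
      stringsAsFactors = FALSE)
    out <- rbind(out, un)
  }
  out <- out[order(out$position, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate middle-down site abundances with a bottom-up table
#'
#' Pearson correlation over the site-modification labels shared by the two
#' tables, per condition when both carry a \code{condition} column.
#'
#' @param middle,bottom Data frames with columns \code{label} and
#'   \code{abundance} (optionally \code{condition}).
#' @return Data frame with columns \code{condition} (\code{"all"} when
#'   conditions are absent), \code{n_shared}, \code{r}; attribute
#'   \code{"shared_labels"} lists the labels used.
#' @export
compare_bottom_up <- function(middle, bottom) {
  has_cond <- "condition" %in% names(middle) && "condition" %in% names(bottom)
  if (!has_cond) {
    middle$condition <- "all"
    bottom$condition <- "all"
  }
  conds <- intersect(unique(middle$condition), unique(bottom$condition))
  if (!length(conds)) stop("no shared conditions", call. = FALSE)
  shared_all <- character(0)
  rows <- lapply(conds, function(cd) {
    m <- middle[middle$condition == cd, ]
    b <- bottom[bottom$condition == cd, ]
    shared <- intersect(m$label, b$label)
    if (length(shared) < 3L) {
      stop("fewer than 3 shared site-modification labels in condition '",
           cd, "'", call. = FALSE)
    }
    shared_all <<- union(shared_all, shared)
    data.frame(condition = cd, n_shared = length(shared),
               r = stats::cor(m$abundance[match(shared, m$label)],
                              b$abundance[match(shared, b$label)],
                              method = "pearson"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "shared_labels") <- sort(shared_all)
  out
}
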