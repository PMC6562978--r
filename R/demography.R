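#' Demographic composition of one group
#'
#' Class proportions with the *total* group membership as denominator,
#' pouch young included — deliberately different from [group_size()], which
#' excludes them; the two denominators are the field's conventions for
#' group size versus composition and are not reconciled here.
#'
#' @param group Data frame of one group's members with `demo_class`, or a
#'   character vector of classes.
#' @return Named numeric vector of six proportions (in [DEMO_CLASSES]
#'   order) summing to 1.
#' @export
group_composition <- function(group) {
  cls <- if (is.data.frame(group)) group$demo_class else group
  if (!length(cls)) stop("empty group")
  bad <- setdiff(unique(cls), DEMO_CLASSES)
  if (length(bad)) stop("unknown demographic class: ", paste(bad, collapse = ", "))
  tab <- table(factor(cls, levels = DEMO_CLASSES))
  stats::setNames(as.numeric(tab) / length(cls), DEMO_CLASSES)
}

#' Per-group composition table for a whole survey
#'
#' Applies the chain rule at each requested distance and computes each
#' group's composition.
#'
#' @param observations Observation table.
#' @param landscape Optional `"mob_landscape"` for zone lookup (otherwise
#'   the members' recorded zone is used).
#' @param chains Chain distances (m).
#' @return Long data frame: session, chain_m, group, zone, size, n_total,
#'   one column per class proportion.
#' @export
survey_compositions <- function(observations, landscape = NULL,
                                chains = c(15, 30, 50)) {
  out <- list()
  for (s in sort(unique(observations$session))) {
    obs_s <- observations[observations$session == s, , drop = FALSE]
    for (ch in chains) {
      part <- assign_groups(obs_s, ch)
      if (!nrow(part$assignment)) next
      grp <- part$assignment$group[match(as.character(obs_s$id),
                                         part$assignment$id)]
      for (g in sort(unique(stats::na.omit(grp)))) {
        gm <- obs_s[which(grp == g), , drop = FALSE]
        comp <- group_composition(gm)
        zone <- if (!is.null(landscape)) {
          ctr <- group_centroid(gm); zone_of(ctr[1], ctr[2], landscape)
        } else unique(gm$zone)[1]
        out[[length(out) + 1L]] <- cbind(
          data.frame(session = s, chain_m = ch, group = g, zone = zone,
                     size = group_size(gm), n_total = nrow(gm)),
          as.data.frame(as.list(comp)))
      }
    }
  }
  do.call(rbind, out)
}

#' Zone-level mean composition
#'
#' Group compositions are averaged unweighted within each session, then
#' across sessions; the standard error is taken across session means. A
#' size-weighted within-session mean is available for sensitivity analysis.
#'
#' @param compositions Output of [survey_compositions()].
#' @param weight_by_size Weight groups by total size within sessions?
#' @return Data frame: zone, chain_m, demo_class, mean, se, n_sessions.
#' @export
mean_composition <- function(compositions, weight_by_size = FALSE) {
  out <- list()
  for (z in sort(unique(compositions$zone))) {
    for (ch in sort(unique(compositions$chain_m))) {
      cc <- compositions[compositions$zone == z & compositions$chain_m == ch, ,
                         drop = FALSE]
      if (!nrow(cc)) next
      sess_means <- lapply(split(cc, cc$session), function(ss) {
        w <- if (weight_by_size) ss$n_total else rep(1, nrow(ss))
        vapply(DEMO_CLASSES, function(k) stats::weighted.mean(ss[[k]], w),
               numeric(1))
      })
      m <- do.call(rbind, sess_means)
      out[[length(out) + 1L]] <- data.frame(
        zone = z, chain_m = ch, demo_class = DEMO_CLASSES,
        mean = colMeans(m),
        se = apply(m, 2, stats::sd) / sqrt(nrow(m)),
        n_sessions = nrow(m), row.names = NULL)
    }
  }
  do.call(rbind, out)
}
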