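# Cohort demographics summary in the style of a clinical Table 1.

fmt_ms <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return("-")
  sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
}

#' Table-1-style demographics summary with group tests
#'
#' Per group (pooled PD, PD without RBD, PD with RBD, healthy controls):
#' n, sex counts (F/M) and mean +/- SD of age and every clinical score,
#' with a Kruskal-Wallis p-value for healthy controls vs pooled PD and
#' for the two PD subgroups; sex rows use the uncorrected chi-square
#' test. Rows where a comparison is undefined (a score absent in a group)
#' carry \code{NA}.
#'
#' @param manifest subject manifest data.frame.
#' @return data.frame with one row per variable and columns
#'   \code{variable}, \code{PD}, \code{PDnonRBD}, \code{PDRBD},
#'   \code{HC}, \code{p_hc_vs_pd}, \code{p_rbd_vs_nonrbd}.
#' @export
demographics_table <- function(manifest) {
  m <- manifest
  is_pd <- m$group %in% c("PDnonRBD", "PDRBD")
  grp <- list(PD = m[is_pd, ], PDnonRBD = m[m$group == "PDnonRBD", ],
              PDRBD = m[m$group == "PDRBD", ], HC = m[m$group == "HC", ])
  score_cols <- setdiff(names(m), c("subject_id", "group", "age", "sex"))

  p_pair <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    kruskal_wallis(list(x, y))$p
  }
  p_sex <- function(a, b) {
    tab <- rbind(c(sum(a$sex == "F"), sum(a$sex == "M")),
                 c(sum(b$sex == "F"), sum(b$sex == "M")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    chi_square_2x2(tab)$p
  }

  rows <- list(
    data.frame(variable = "n", PD = nrow(grp$PD),
               PDnonRBD = nrow(grp$PDnonRBD), PDRBD = nrow(grp$PDRBD),
               HC = nrow(grp$HC), p_hc_vs_pd = NA_real_,
               p_rbd_vs_nonrbd = NA_real_, stringsAsFactors = FALSE),
    data.frame(
      variable = "sex_F_M",
      PD = paste0(sum(grp$PD$sex == "F"), "/", sum(grp$PD$sex == "M")),
      PDnonRBD = paste0(sum(grp$PDnonRBD$sex == "F"), "/",
                        sum(grp$PDnonRBD$sex == "M")),
      PDRBD = paste0(sum(grp$PDRBD$sex == "F"), "/",
                     sum(grp$PDRBD$sex == "M")),
      HC = paste0(sum(grp$HC$sex == "F"), "/", sum(grp$HC$sex == "M")),
      p_hc_vs_pd = p_sex(grp$PD, grp$HC),
      p_rbd_vs_nonrbd = p_sex(grp$PDnonRBD, grp$PDRBD),
      stringsAsFactors = FALSE)
  )
  for (v in c("age", score_cols)) {
    rows[[v]] <- data.frame(
      variable = v,
      PD = fmt_ms(grp$PD[[v]]), PDnonRBD = fmt_ms(grp$PDnonRBD[[v]]),
      PDRBD = fmt_ms(grp$PDRBD[[v]]), HC = fmt_ms(grp$HC[[v]]),
      p_hc_vs_pd = p_pair(grp$HC[[v]], grp$PD[[v]]),
      p_rbd_vs_nonrbd = p_pair(grp$PDnonRBD[[v]], grp$PDRBD[[v]]),
      stringsAsFactors = FALSE)
  }
  rows <- lapply(rows, function(r) { r$PD <- as.character(r$PD)
    r$PDnonRBD <- as.character(r$PDnonRBD)
    r$PDRBD <- as.character(r$PDRBD); r$HC <- as.character(r$HC); r })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
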