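# Multi-round registered immunofluorescence colocalization: align repeated
# staining rounds on one field via their DIC landmarks, build a
# per-terminal protein table, and compute the normalized quantity indices
# Q and sum-Q.

#' Assemble a multi-round staining set
#'
#' Each round carries a DIC landmark image and 2-3 protein channels; all
#' images show the same field at the same pixel size, and channel names are
#' unique across rounds.
#'
#' @param rounds List of `list(dic = ImageStack, channels = named list of
#'   ImageStack)`.
#' @return A `RoundSet`.
#' @export
round_set <- function(rounds) {
  stopifnot(length(rounds) >= 1L)
  nm <- unlist(lapply(rounds, function(r) names(r$channels)))
  if (anyDuplicated(nm)) {
    stop_mgs("channel names must be unique across rounds (duplicated: %s)",
             paste(unique(nm[duplicated(nm)]), collapse = ", "),
             class = "mgsynapse_validation_error")
  }
  th <- unique(round(unlist(lapply(rounds, function(r) {
    c(r$dic$theta, vapply(r$channels, function(ch) ch$theta, numeric(1)))
  })), 9))
  if (length(th) != 1L) {
    stop_mgs("all images in a RoundSet must share one pixel size",
             class = "mgsynapse_validation_error")
  }
  structure(list(rounds = rounds, theta = th), class = "RoundSet")
}

#' Align all staining rounds onto the first round's frame
#'
#' Each round's transform is estimated DIC-to-reference-DIC and applied to
#' that round's protein channels. Rounds that cannot be registered raise an
#' error naming the round.
#'
#' @param rs A [round_set()].
#' @param mode `"rigid"` or `"elastic"` (passed to [register()]).
#' @return The aligned `RoundSet`; each round gains `transform` and
#'   `residual_ncc` fields.
#' @export
align_rounds <- function(rs, mode = "rigid") {
  stopifnot(inherits(rs, "RoundSet"))
  ref <- rs$rounds[[1L]]$dic
  for (i in seq_along(rs$rounds)) {
    tf <- tryCatch(
      register(ref, rs$rounds[[i]]$dic, mode = mode),
      mgsynapse_registration_error = function(e) {
        stop_mgs("round %d is unregistrable: %s", i, conditionMessage(e),
                 class = "mgsynapse_registration_error")
      })
    rs$rounds[[i]]$transform <- tf
    rs$rounds[[i]]$residual_ncc <- tf$ncc
    rs$rounds[[i]]$dic <- apply_transform(rs$rounds[[i]]$dic, tf)
    rs$rounds[[i]]$channels <- lapply(rs$rounds[[i]]$channels,
                                      apply_transform, tf = tf)
  }
  rs$aligned <- TRUE
  rs
}

all_channels <- function(rs) {
  out <- list()
  for (r in rs$rounds) out <- c(out, r$channels)
  out
}

#' Build the per-terminal protein table
#'
#' Structural puncta (from `structural_channel`, typically SYP) define the
#' rows. Every other protein channel is punctum-detected and matched to the
#' structural puncta within `radius`; matched integrated fluorescence is
#' assigned to the row and unmatched rows record 0 (a terminal genuinely
#' lacking a protein scores zero rather than missing). Optional FM deltaF
#' images contribute response columns the same way, and the 5AP response
#' sets the functional label.
#'
#' @param rs An aligned [round_set()].
#' @param structural_channel Channel defining terminals (default "SYP").
#' @param radius Punctum-to-terminal assignment radius (micron; default
#'   0.5, configurable — about twice the expected registration error).
#' @param fm Optional named list of deltaF [image_stack()]s, e.g.
#'   `list(FM5AP =, FM600AP =)`, already in the reference frame.
#' @param ... Passed to [detect_puncta()].
#' @return A `TerminalTable` data frame: position, structural F, one `q_*`
#'   column per protein, optional `fm_*` columns, `functional`, `label`.
#' @export
build_terminal_table <- function(rs, structural_channel = "SYP",
                                 radius = 0.5, fm = NULL, ...) {
  stopifnot(inherits(rs, "RoundSet"))
  chans <- all_channels(rs)
  if (!structural_channel %in% names(chans)) {
    stop_mgs("structural channel '%s' missing (have: %s)",
             structural_channel, paste(names(chans), collapse = ", "),
             class = "mgsynapse_validation_error")
  }
  structural <- detect_puncta(chans[[structural_channel]], ...)
  tab <- data.frame(terminal = seq_len(nrow(structural)),
                    x_um = structural$x_um, y_um = structural$y_um,
                    F_structural = structural$F, check.names = FALSE)
  assign_channel <- function(img, colname) {
    p <- detect_puncta(img, ...)
    v <- numeric(nrow(tab))
    if (nrow(p) > 0L && nrow(tab) > 0L) {
      m <- match_puncta(structural, p, radius = radius)
      v[m$pairs$i] <- p$F[m$pairs$j]
    }
    tab[[colname]] <<- v
  }
  for (nm in setdiff(names(chans), structural_channel)) {
    assign_channel(chans[[nm]], paste0("q_", nm))
  }
  p5 <- NULL
  if (!is.null(fm)) {
    for (nm in names(fm)) {
      p <- detect_puncta(fm[[nm]], ...)
      v <- numeric(nrow(tab))
      if (nrow(p) > 0L && nrow(tab) > 0L) {
        m <- match_puncta(structural, p, radius = radius)
        v[m$pairs$i] <- p$F[m$pairs$j]
      }
      tab[[paste0("fm_", nm)]] <- v
      if (grepl("5AP", nm, ignore.case = TRUE)) p5 <- p
    }
  }
  if (!is.null(p5)) {
    cls <- classify_terminals(structural, p5, radius = radius)
    tab$functional <- cls$functional
    tab$label <- cls$label
  }
  class(tab) <- c("TerminalTable", "data.frame")
  tab
}

#' Normalized protein quantity Q
#'
#' `Q_p` is a condition's fluorescence-per-area for protein p divided by
#' the control-group mean for the same protein; the control group has mean
#' Q of exactly 1 per protein by construction.
#'
#' @param aoi_fluor_per_area Named numeric: total punctum fluorescence per
#'   unit MAP2 area for each protein.
#' @param control_means Named numeric: control-group means per protein
#'   (all positive).
#' @return Named numeric vector of Q values.
#' @export
protein_q <- function(aoi_fluor_per_area, control_means) {
  nm <- names(aoi_fluor_per_area)
  missing <- setdiff(nm, names(control_means))
  if (length(missing) > 0L) {
    stop_mgs("no control mean for: %s", paste(missing, collapse = ", "),
             class = "mgsynapse_validation_error")
  }
  cm <- control_means[nm]
  if (any(!is.finite(cm)) || any(cm <= 0)) {
    stop_mgs("control means must all be positive",
             class = "mgsynapse_validation_error")
  }
  aoi_fluor_per_area / cm
}

#' Total Ca2+-sensitivity-protein quantity
#'
#' `sumQ = Q_SYT1 + Q_Rab3a + Q_RIM1 + Q_Munc13-1 + Q_ELKS + Q_Syntaxin1`,
#' plus its ratio to the structural quantity `Q_SYP` when SYP is present.
#'
#' @param q Named numeric of Q values containing all six Ca2+-sensitivity
#'   proteins.
#' @return `list(sum_q =, ratio_to_syp =)` (`ratio_to_syp` is `NA` without
#'   SYP).
#' @export
sum_q <- function(q) {
  need <- ca_sensitivity_proteins()
  absent <- setdiff(need, names(q))
  if (length(absent) > 0L) {
    stop_mgs("missing protein channel(s): %s", paste(absent, collapse = ", "),
             class = "mgsynapse_validation_error")
  }
  s <- sum(q[need])
  list(sum_q = s,
       ratio_to_syp = if ("SYP" %in% names(q)) s / q[["SYP"]] else NA_real_)
}

#' Protein profile of nonfunctional vs functional terminals
#'
#' Summarizes each protein column of a terminal table by functional label:
#' group means, Cohen's d effect size, and a two-sample t test; and, per
#' nonfunctional terminal, which proteins fall below a configurable
#' quantile of the functional-terminal distribution ("depleted").
#'
#' @param table A [build_terminal_table()] result with a `label` column.
#' @param depletion_quantile Depletion cut as a quantile of the functional
#'   distribution (default 0.25).
#' @return `list(summary = data.frame, depleted = logical matrix
#'   (nonfunctional terminals x proteins), absent_class = NULL or the
#'   missing label)`.
#' @export
profile_nonfunctional <- function(table, depletion_quantile = 0.25) {
  if (!"label" %in% names(table)) {
    stop_mgs("terminal table has no functional labels",
             class = "mgsynapse_validation_error")
  }
  prot_cols <- grep("^q_", names(table), value = TRUE)
  fun <- table$label == "functional"
  if (all(fun) || all(!fun)) {
    return(list(summary = NULL, depleted = NULL,
                absent_class = if (all(fun)) "nonfunctional" else "functional"))
  }
  rows <- lapply(prot_cols, function(cl) {
    a <- table[[cl]][fun]; b <- table[[cl]][!fun]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    p <- if (length(a) >= 2L && length(b) >= 2L) {
      compare_groups(a, b, "t")$p_value
    } else NA_real_
    data.frame(protein = sub("^q_", "", cl),
               mean_functional = mean(a), mean_nonfunctional = mean(b),
               cohens_d = if (sp > 0) (mean(a) - mean(b)) / sp else NA_real_,
               p_value = p)
  })
  summary <- do.call(rbind, rows)
  cuts <- vapply(prot_cols, function(cl) {
    stats::quantile(table[[cl]][fun], depletion_quantile, names = FALSE)
  }, numeric(1))
  depleted <- do.call(cbind, lapply(seq_along(prot_cols), function(k) {
    table[[prot_cols[k]]][!fun] < cuts[k]
  }))
  colnames(depleted) <- sub("^q_", "", prot_cols)
  list(summary = summary, depleted = depleted, absent_class = NULL)
}
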