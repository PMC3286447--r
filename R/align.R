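#' Align per-sample peak lists into a feature table
#'
#' Greedy nearest-centroid clustering: peaks pooled over all samples are
#' visited in (mass, rt) order and attached to the closest existing
#' cluster whose running intensity-weighted centroid lies within `ppm_tol`
#' (relative mass) and `rt_tol` (absolute retention time); otherwise a new
#' cluster is opened. Each sample contributes at most one peak per
#' cluster: on collision the more intense peak wins and the loser is
#' re-routed to the next-nearest admissible cluster or a new one. Final
#' clusters are sorted by centroid mass then rt.
#'
#' @param peak_lists named list of data.frames with columns `mass`, `rt`,
#'   `intensity` (as produced by [generate_peak_lists()] or read from
#'   per-sample CSVs).
#' @param ppm_tol mass window in ppm (> 0).
#' @param rt_tol retention-time window in minutes (> 0).
#' @param sample_labels optional named character vector of class labels;
#'   defaults to the `"sample_labels"` attribute of `peak_lists`, then to
#'   `"P"`.
#' @return A [feature_table()]; when the input peaks carry a
#'   `source_feature` column, per-cluster provenance is attached as
#'   attribute `"cluster_members"` for alignment scoring.
#' @export
align_peak_lists <- function(peak_lists, ppm_tol, rt_tol,
                             sample_labels = NULL) {
  if (!is_number(ppm_tol) || ppm_tol <= 0) abort("ppm_tol must be > 0")
  if (!is_number(rt_tol) || rt_tol <= 0) abort("rt_tol must be > 0")
  sample_ids <- names(peak_lists) %||%
    sprintf("S%03d", seq_along(peak_lists))
  labels <- sample_labels %||% attr(peak_lists, "sample_labels")
  labels <- if (is.null(labels)) {
    rep("P", length(sample_ids))
  } else {
    unname(labels[sample_ids])
  }

  pooled <- do.call(rbind, lapply(seq_along(peak_lists), function(j) {
    pl <- peak_lists[[j]]
    if (is.null(pl) || nrow(pl) == 0) return(NULL)
    data.frame(
      sample = j, mass = pl$mass, rt = pl$rt, intensity = pl$intensity,
      source = if ("source_feature" %in% names(pl)) {
        pl$source_feature
      } else {
        NA_character_
      }
    )
  }))
  samples_df <- data.frame(sample_id = sample_ids, label = labels)
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(feature_table(
      data.frame(feature_id = character(), neutral_mass = numeric(),
                 rt = numeric()),
      samples_df,
      matrix(numeric(), 0, length(sample_ids))
    ))
  }
  pooled <- pooled[order(pooled$mass, pooled$rt, -pooled$intensity), ,
                   drop = FALSE]

  cent_mass <- numeric(0)
  cent_rt <- numeric(0)
  members <- list() # per cluster: data.frame(sample, mass, rt, intensity, source)

  recompute <- function(m) {
    w <- m$intensity / sum(m$intensity)
    c(sum(w * m$mass), sum(w * m$rt))
  }

  place <- function(peak, exclude = integer(0)) {
    # returns updated state via <<-; may recurse once per displaced peak
    repeat {
      cand <- which(
        abs(peak$mass - cent_mass) / cent_mass * 1e6 <= ppm_tol &
          abs(peak$rt - cent_rt) <= rt_tol
      )
      cand <- setdiff(cand, exclude)
      if (length(cand) == 0) {
        members[[length(members) + 1L]] <<- peak
        cent_mass[length(members)] <<- peak$mass
        cent_rt[length(members)] <<- peak$rt
        return(invisible())
      }
      k <- cand[which.min(abs(peak$mass - cent_mass[cand]))]
      m <- members[[k]]
      dup <- which(m$sample == peak$sample)
      if (length(dup) == 0) {
        m <- rbind(m, peak)
        members[[k]] <<- m
        cm <- recompute(m)
        cent_mass[k] <<- cm[1]
        cent_rt[k] <<- cm[2]
        return(invisible())
      }
      if (peak$intensity > m$intensity[dup]) {
        loser <- m[dup, , drop = FALSE]
        m[dup, ] <- peak
        members[[k]] <<- m
        cm <- recompute(m)
        cent_mass[k] <<- cm[1]
        cent_rt[k] <<- cm[2]
        peak <- loser
      }
      exclude <- c(exclude, k)
    }
  }

  for (i in seq_len(nrow(pooled))) {
    place(pooled[i, , drop = FALSE])
  }

  ord <- order(cent_mass, cent_rt)
  members <- members[ord]
  n_cl <- length(members)
  mat <- matrix(NA_real_, n_cl, length(sample_ids))
  for (k in seq_len(n_cl)) {
    m <- members[[k]]
    mat[k, m$sample] <- m$intensity
  }
  feats <- data.frame(
    feature_id = sprintf("F%05d", seq_len(n_cl)),
    neutral_mass = cent_mass[ord],
    rt = cent_rt[ord]
  )
  out <- feature_table(feats, samples_df, mat)
  if (!all(is.na(pooled$source))) {
    attr(out, "cluster_members") <- lapply(members, function(m) {
      data.frame(sample = sample_ids[m$sample], source_feature = m$source)
    })
  }
  out
}

#' Write per-sample peak lists as CSV files
#'
#' One `mass,rt,intensity` CSV per sample, named `<sample_id>.csv`.
#'
#' @param peak_lists named list as from [generate_peak_lists()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_peak_lists <- function(peak_lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(peak_lists), function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    utils::write.csv(
      peak_lists[[id]][, c("mass", "rt", "intensity")], p,
      row.names = FALSE, quote = FALSE
    )
    p
  }, "")
  invisible(paths)
}
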