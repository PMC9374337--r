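#' Group localizations into stroboscopic frame couples
#'
#' Frames are paired as disjoint consecutive couples starting at the given
#' phase: phase 0 gives couples (0,1), (2,3), ...; phase 1 gives (1,2),
#' (3,4), .... Localizations in frames before the phase are left unpaired.
#'
#' @param localizations data.frame with columns `frame`, `x_nm`, `y_nm`
#'   (extra columns are carried along).
#' @param phase 0 or 1.
#' @return list of couples, each `list(couple = index, first = df,
#'   second = df)`; empty input gives an empty list.
#' @export
pairFrames <- function(localizations, phase = 0L) {
  phase <- as.integer(phase)
  if (!phase %in% c(0L, 1L)) stop("phase must be 0 or 1")
  if (is.null(localizations) || nrow(localizations) == 0L) return(list())
  f <- localizations$frame
  eligible <- f >= phase
  cid <- (f - phase) %/% 2L
  role <- (f - phase) %% 2L
  ids <- sort(unique(cid[eligible]))
  out <- lapply(ids, function(k) {
    list(couple = k,
         first = localizations[eligible & cid == k & role == 0L, ,
                               drop = FALSE],
         second = localizations[eligible & cid == k & role == 1L, ,
                                drop = FALSE])
  })
  # a couple needs detections in both of its frames; a lone trailing frame
  # stays unpaired
  out[vapply(out, function(cp) nrow(cp$first) > 0L && nrow(cp$second) > 0L,
             logical(1))]
}

#' All-pairs peak matching within one frame couple
#'
#' Every peak in the first frame is matched with every peak of the second
#' frame lying within `rMax`; ambiguous assignments are deliberately kept
#' (not resolved to nearest neighbours), since misassigned pairs are modelled
#' downstream by the linear background term of the displacement PDF.
#'
#' @param couple one element of the list returned by [pairFrames()].
#' @param rMax maximum pairing distance in nm (default 600).
#' @return displacement data.frame (`origin_x_nm`, `origin_y_nm`, `end_x_nm`,
#'   `end_y_nm`, `r_nm`, `couple`), anchored at the first-frame positions.
#' @export
pairPeaks <- function(couple, rMax = 600) {
  if (rMax <= 0) stop("rMax must be > 0")
  a <- couple$first
  b <- couple$second
  empty <- data.frame(origin_x_nm = numeric(0), origin_y_nm = numeric(0),
                      end_x_nm = numeric(0), end_y_nm = numeric(0),
                      r_nm = numeric(0), couple = integer(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  dx <- outer(a$x_nm, b$x_nm, function(p, q) q - p)
  dy <- outer(a$y_nm, b$y_nm, function(p, q) q - p)
  r <- sqrt(dx^2 + dy^2)
  keep <- which(r <= rMax, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(empty)
  out <- data.frame(origin_x_nm = a$x_nm[keep[, 1]],
                    origin_y_nm = a$y_nm[keep[, 1]],
                    end_x_nm = b$x_nm[keep[, 2]],
                    end_y_nm = b$y_nm[keep[, 2]],
                    r_nm = r[keep], couple = couple$couple)
  if (!is.null(a$truth_id) && !is.null(b$truth_id)) {
    ta <- a$truth_id[keep[, 1]]
    tb <- b$truth_id[keep[, 2]]
    out$truth_ok <- !is.na(ta) & !is.na(tb) & ta == tb
  }
  out
}

#' Extract displacements from a localization stream
#'
#' Convenience chain: [pairFrames()] then [pairPeaks()] for every couple.
#'
#' @inheritParams pairFrames
#' @inheritParams pairPeaks
#' @return displacement data.frame across all couples.
#' @export
extractDisplacements <- function(localizations, rMax = 600, phase = 0L) {
  couples <- pairFrames(localizations, phase)
  out <- do.call(rbind, lapply(couples, pairPeaks, rMax = rMax))
  if (is.null(out))
    out <- data.frame(origin_x_nm = numeric(0), origin_y_nm = numeric(0),
                      end_x_nm = numeric(0), end_y_nm = numeric(0),
                      r_nm = numeric(0), couple = integer(0))
  rownames(out) <- NULL
  out
}

#' Filter displacements to the truncation bound
#'
#' Keeps displacements with length at most `rMax` (boundary inclusive; the model PDF is
#' normalized over `[0, rMax]`, so the same bound must be applied to the
#' data before fitting).
#'
#' @param displacements displacement data.frame.
#' @param rMax bound in nm.
#' @return the retained subset.
#' @export
filterDisplacements <- function(displacements, rMax = 600) {
  out <- displacements[displacements$r_nm <= rMax, , drop = FALSE]
  rownames(out) <- NULL
  out
}
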