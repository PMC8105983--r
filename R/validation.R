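best_hit <- function(cand, family) {
  h <- cand$hits[cand$hits$family == family, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h[which.max(h$bits), , drop = FALSE]
}

#' Validate a LuxR candidate by domain architecture
#'
#' A LuxR candidate is `VALID` iff it carries both the autoinducer-binding
#' and the helix-turn-helix (HTH) hits at or above `bits_threshold`, with
#' the ligand-binding envelope starting N-terminal of the HTH envelope
#' (signal-binding domain at the N terminus, DNA-binding HTH at the C
#' terminus); otherwise `INVALID` with a reason.  Idempotent.
#'
#' @param cand a `qs_candidate` with `family_call == "LUXR"`.
#' @param bits_threshold acceptance threshold in bits (default 50).
#' @return the candidate with `validation_status` and `reason` set.
#' @export
validate_luxr <- function(cand, bits_threshold = 50) {
  stopifnot(inherits(cand, "qs_candidate"))
  if (cand$family_call != "LUXR")
    stop("validate_luxr() requires family_call LUXR, got ", cand$family_call)
  ab <- best_hit(cand, "LUXR_AUTOIND_BIND")
  hth <- best_hit(cand, "LUXR_HTH")
  ok_ab <- !is.null(ab) && ab$bits >= bits_threshold
  ok_hth <- !is.null(hth) && hth$bits >= bits_threshold
  if (ok_ab && ok_hth) {
    if (ab$q_start < hth$q_start) {
      cand$validation_status <- "VALID"; cand$reason <- "ok"
    } else {
      cand$validation_status <- "INVALID"; cand$reason <- "domain order"
    }
  } else {
    cand$validation_status <- "INVALID"
    cand$reason <- paste("missing",
                         paste(c("ligand-binding domain", "HTH domain")
                               [!c(ok_ab, ok_hth)], collapse = " and "))
  }
  cand
}

#' Validate a LuxI candidate, with conserved-residue rescue
#'
#' A LuxI candidate is `VALID` iff both the synthase-family and the
#' conserved-site hits reach `bits_threshold`.  When the synthase hit
#' passes but the conserved-site evidence is missing, the candidate is
#' rescued to `VALID_BY_RESIDUE_RESCUE` iff every position of the LuxI
#' rule set has status `match` (complete consensus with the conserved
#' residues; a gap counts as non-match).  Otherwise `INVALID`.  Idempotent,
#' and monotone: adding a conserved-site hit never downgrades a rescued
#' candidate.
#'
#' @param cand a `qs_candidate` with `family_call == "LUXI"`;
#'   `residue_checks` (TraI numbering) must be populated when the rescue
#'   path is reached.
#' @param bits_threshold acceptance threshold in bits (default 50).
#' @return the candidate with `validation_status` and `reason` set.
#' @export
validate_luxi <- function(cand, bits_threshold = 50) {
  stopifnot(inherits(cand, "qs_candidate"))
  if (cand$family_call != "LUXI")
    stop("validate_luxi() requires family_call LUXI, got ", cand$family_call)
  syn <- best_hit(cand, "LUXI_SYNTHASE")
  site <- best_hit(cand, "LUXI_CONSERVED_SITE")
  ok_syn <- !is.null(syn) && syn$bits >= bits_threshold
  ok_site <- !is.null(site) && site$bits >= bits_threshold
  if (ok_syn && ok_site) {
    cand$validation_status <- "VALID"; cand$reason <- "ok"
  } else if (ok_syn) {
    if (is.null(cand$residue_checks))
      stop("residue checks required for the conserved-residue rescue of ",
           cand$gene$gene_id)
    if (all(cand$residue_checks$status == "match")) {
      cand$validation_status <- "VALID_BY_RESIDUE_RESCUE"
      cand$reason <- "conserved-site hit missing; complete residue consensus"
    } else {
      cand$validation_status <- "INVALID"
      cand$reason <- "conserved-site hit missing; incomplete residue consensus"
    }
  } else {
    cand$validation_status <- "INVALID"
    cand$reason <- "missing synthase-family hit"
  }
  cand
}
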