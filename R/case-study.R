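# Arsenic fish-ingestion non-cancer risk: the packaged worked example.
#
# Produced water discharged at sea carries arsenic; people are exposed by
# eating contaminated fish. The exposure model is the standard food-chain
# chronic-daily-intake chain: fish-tissue concentration Cf = PEC x BCF,
# CDI = Cf x FIR x FR x EF x ED x CF / (BW x AT), and the non-cancer hazard
# quotient Risk = CDI / Rfd. PEC and BCF are epistemic (fuzzy), BW is
# aleatory (normal), everything else constant.

#' Fish-tissue chemical concentration
#'
#' `Cf = PEC * BCF`: the predicted environmental concentration in water
#' times the bioaccumulation factor in fish.
#'
#' @param pec Predicted environmental concentration (ug/l as tabulated).
#' @param bcf Bioaccumulation factor (l/kg).
#' @return Tissue concentration, in the product units.
#' @export
fish_tissue_conc <- function(pec, bcf) pec * bcf

#' Chronic daily intake
#'
#' `CDI = Cf * FIR * FR * EF * ED * CF * intake_unit_factor / (BW * AT)`.
#' The `intake_unit_factor` of 1e-3 converts the fish ingestion rate from
#' g/day to kg/day so that CDI comes out in mg/(kg day), commensurate with
#' the reference dose; it is exposed rather than folded into `cf_factor`
#' so the unit convention stays visible and adjustable.
#'
#' @param cf Fish-tissue concentration from [fish_tissue_conc()].
#' @param bw Body weight (kg).
#' @param fir Fish ingestion rate (g/day). Default 170.
#' @param fr Fraction of fish from the contaminated source. Default 0.5.
#' @param ef Exposure frequency (days/year). Default 350.
#' @param ed Exposure duration (years). Default 30.
#' @param cf_factor Conversion factor. Default 1e-9.
#' @param at Averaging time (days). Default 25550.
#' @param intake_unit_factor Ingestion-rate unit conversion. Default 1e-3.
#' @return Chronic daily intake, mg/(kg day).
#' @examples
#' chronic_daily_intake(fish_tissue_conc(4, 35), bw = 70,
#'                      intake_unit_factor = 1) # 6.9866e-08
#' @export
chronic_daily_intake <- function(cf, bw, fir = 170, fr = 0.5, ef = 350,
                                 ed = 30, cf_factor = 1e-9, at = 25550,
                                 intake_unit_factor = 1e-3) {
  stopifnot(all(bw > 0), at > 0)
  cf * fir * fr * ef * ed * cf_factor * intake_unit_factor / (bw * at)
}

#' Non-cancer risk (hazard quotient)
#'
#' `Risk = CDI / Rfd`: chronic daily intake over the oral reference dose.
#' Strictly increasing in `pec` and `bcf` and strictly decreasing in `bw`,
#' so corner (vertex) evaluation of the fuzzy parameters is exact for this
#' model.
#'
#' @param pec,bcf,bw Exposure inputs; see [fish_tissue_conc()] and
#'   [chronic_daily_intake()].
#' @param rfd Oral reference dose, mg/(kg day). Default 3e-4 (arsenic).
#' @param ... Constants passed on to [chronic_daily_intake()].
#' @return Hazard quotient (unitless).
#' @examples
#' noncancer_risk(pec = 4, bcf = 35, bw = 70)   # 2.3288e-07
#' @export
noncancer_risk <- function(pec, bcf, bw, rfd = 3e-4, ...) {
  stopifnot(rfd > 0)
  chronic_daily_intake(fish_tissue_conc(pec, bcf), bw, ...) / rfd
}

#' The arsenic case-study model
#'
#' The packaged worked example: non-cancer risk from ingesting
#' arsenic-contaminated fish, with
#' * constants AT = 25550 d, ED = 30 y, EF = 350 d/y, FR = 0.5,
#'   FIR = 170 g/day, CF = 1e-9, Rfd = 3e-4 mg/(kg day);
#' * body weight BW ~ Normal(70, 5) kg (aleatory);
#' * PEC, the triangular generalized fuzzy number `[4, 5, 6; 0.8]` ug/l
#'   (epistemic, with partial confidence 0.8);
#' * BCF, the normal interval-valued fuzzy number with UMF `[35, 45, 55]`
#'   and LMF `[40, 45, 50]` l/kg.
#'
#' One parameter at 0.8 height makes the alpha sweep run to w = 0.8, and all
#' fractile membership functions of the risk come out as height-0.8
#' trapezoids.
#'
#' @param intake_unit_factor Ingestion-rate unit conversion applied inside
#'   the intake equation; default 1e-3 (g/day to kg/day).
#' @return A [hybrid_model()] named `"arsenic"`, ready for [propagate()].
#' @examples
#' fam <- propagate(arsenic_model(), n_mc = 500, seed = 1)
#' glance(pbox(fam, "umf"))
#' @export
arsenic_model <- function(intake_unit_factor = 1e-3) {
  force(intake_unit_factor)
  hybrid_model(
    evaluator = function(PEC, BCF, BW) {
      noncancer_risk(PEC, BCF, BW, intake_unit_factor = intake_unit_factor)
    },
    params = list(
      PEC = gfn(4, 5, 6, height = 0.8),
      BCF = ivfn(umf = gfn(35, 45, 55), lmf = gfn(40, 45, 50)),
      BW = dist_normal(70, 5)
    ),
    name = "arsenic"
  )
}
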