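# Shared fixtures, built in code at test time.

base_params <- function(...) sarc_parameters(...)

# Constant-mortality variant (flat 0.09 per cycle in the healthy arm).
const_params <- function(...) sarc_parameters(..., mortality = "constant")

# Published base-case cost-effectiveness results used as arithmetic inputs
# for identity checks (costs in USD, effects in QALYs, reference values for
# ICER/NMB/dominance identities).
reference_cea <- function() {
  data.frame(
    strategy = c("NoScreening", "SARC-F", "SarSA-Mod", "MSRA", "EWGSOP"),
    cost = c(1455.07, 1809.41, 3140.83, 3151.27, 3518.75),
    effect = c(7.40, 7.59, 8.30, 8.30, 8.50),
    nmb_printed = c(39404.3, 40080.6, 42663.3, 42640.6, 43414.3),
    stringsAsFactors = FALSE)
}

REF_WTP <- 5520.311
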