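# Zygosity-by-sex group labels used throughout. Opposite-sex groups are
# ordered proband-first: "DZ-FM" means female twin 1 (proband), male twin 2.
.same_sex_groups <- c("MZ-FF", "MZ-MM", "DZ-FF", "DZ-MM")
.opp_sex_groups <- c("DZ-FM", "DZ-MF")
.zygosity_groups <- c(.same_sex_groups, .opp_sex_groups)

`%||%` <- function(a, b) if (is.null(a)) b else a
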