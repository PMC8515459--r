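# Synthetic stand-in for a 68-composition total plasma N-glycome panel.
# Constructed, not transcribed: the original curated panel is not publicly
# available. Covers high-mannose Man4-Man9, hybrid, and complex mono- to
# tetra-antennary species with fucosylation, bisection and
# linkage-differentiated sialylation (L = alpha2,3; E = alpha2,6).
# Overrides pin the classic agalactosylated diantennary species (N4 with
# H <= 4, e.g. the IgG G0/G0F compositions) to non-bisected A2, which the
# generic rule table would otherwise read as bisected monoantennary.
composition	override_class	override_antennarity	override_bisected
H4N2	NA	NA	NA
H5N2	NA	NA	NA
H6N2	NA	NA	NA
H7N2	NA	NA	NA
H8N2	NA	NA	NA
H9N2	NA	NA	NA
H5N3	NA	NA	NA
H6N3	NA	NA	NA
H7N3	NA	NA	NA
H5N3F1	NA	NA	NA
H6N3E1	NA	NA	NA
H6N3L1	NA	NA	NA
H3N3	NA	NA	NA
H4N3	NA	NA	NA
H3N3F1	NA	NA	NA
H4N3F1	NA	NA	NA
H4N3E1	NA	NA	NA
H3N4	complex	2	FALSE
H3N4F1	complex	2	FALSE
H4N4	complex	2	FALSE
H4N4F1	complex	2	FALSE
H4N4F1E1	complex	2	FALSE
H5N4	NA	NA	NA
H5N4F1	NA	NA	NA
H5N4E1	NA	NA	NA
H5N4L1	NA	NA	NA
H5N4E2	NA	NA	NA
H5N4L2	NA	NA	NA
H5N4E1L1	NA	NA	NA
H5N4F1E1	NA	NA	NA
H5N4F1L1	NA	NA	NA
H5N4F1E2	NA	NA	NA
H5N4F1L2	NA	NA	NA
H5N4F1E1L1	NA	NA	NA
H3N5	NA	NA	NA
H3N5F1	NA	NA	NA
H4N5	NA	NA	NA
H4N5F1	NA	NA	NA
H5N5	NA	NA	NA
H5N5F1	NA	NA	NA
H5N5F1E1	NA	NA	NA
H6N5	NA	NA	NA
H6N5F1	NA	NA	NA
H6N5E1	NA	NA	NA
H6N5L1	NA	NA	NA
H6N5E2	NA	NA	NA
H6N5L2	NA	NA	NA
H6N5E3	NA	NA	NA
H6N5E1L1	NA	NA	NA
H6N5F1E1	NA	NA	NA
H6N5F1E2	NA	NA	NA
H6N5F1L1	NA	NA	NA
H6N6	NA	NA	NA
H6N6F1	NA	NA	NA
H7N6	NA	NA	NA
H7N6F1	NA	NA	NA
H7N6E1	NA	NA	NA
H7N6E2	NA	NA	NA
H7N6E3	NA	NA	NA
H7N6E4	NA	NA	NA
H7N6L1	NA	NA	NA
H7N6E2L1	NA	NA	NA
H7N6F1E1	NA	NA	NA
H7N6F1E2	NA	NA	NA
H7N6F1E3	NA	NA	NA
H7N6F1E4	NA	NA	NA
H7N6F1L1	NA	NA	NA
H7N6F1E2L1	NA	NA	NA
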