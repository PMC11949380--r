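# Register-based lifetime risk of cardiovascular disease at age 40 for the
# Finnish population, 1996-2020, in percent at the published integer
# precision. One row per period x subgroup; subgroup coding as in
# finland_cvd_expectancies_1996_2020.csv.
period,subgroup,lifetime_risk_pct
1996-2000,total,69
2001-2005,total,71
2006-2010,total,72
2011-2015,total,72
2016-2020,total,72
1996-2000,women,68
2001-2005,women,70
2006-2010,women,71
2011-2015,women,71
2016-2020,women,71
1996-2000,men,69
2001-2005,men,71
2006-2010,men,72
2011-2015,men,73
2016-2020,men,73
1996-2000,women_basic,71
2001-2005,women_basic,73
2006-2010,women_basic,74
2011-2015,women_basic,74
2016-2020,women_basic,74
1996-2000,women_secondary,63
2001-2005,women_secondary,66
2006-2010,women_secondary,67
2011-2015,women_secondary,67
2016-2020,women_secondary,67
1996-2000,women_tertiary,58
2001-2005,women_tertiary,61
2006-2010,women_tertiary,62
2011-2015,women_tertiary,63
2016-2020,women_tertiary,63
1996-2000,men_basic,71
2001-2005,men_basic,72
2006-2010,men_basic,74
2011-2015,men_basic,74
2016-2020,men_basic,74
1996-2000,men_secondary,66
2001-2005,men_secondary,68
2006-2010,men_secondary,68
2011-2015,men_secondary,69
2016-2020,men_secondary,69
1996-2000,men_tertiary,68
2001-2005,men_tertiary,70
2006-2010,men_tertiary,71
2011-2015,men_tertiary,71
2016-2020,men_tertiary,72
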