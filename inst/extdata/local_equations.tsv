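sex	outcome	branch	term	coefficient	variant
male	fev1	young	intercept	-25.857	corrected
male	fev1	young	age	0.0285	corrected
male	fev1	young	height	0.296	corrected
male	fev1	young	height2	-0.000728	corrected
male	fev1	old	intercept	-25.144	corrected
male	fev1	old	age_minus_knot	-0.0288	corrected
male	fev1	old	height	0.296	corrected
male	fev1	old	height2	-0.000728	corrected
female	fev1	young	intercept	-2.546	corrected
female	fev1	young	age	0.0082	corrected
female	fev1	young	height	0.0343	corrected
female	fev1	old	intercept	-2.342	corrected
female	fev1	old	age_minus_knot	-0.0232	corrected
female	fev1	old	height	0.0343	corrected
male	ln_fvc	young	intercept	-13.518	corrected
male	ln_fvc	young	age	0.0196	corrected
male	ln_fvc	young	height	0.156	corrected
male	ln_fvc	young	height2	-0.00041	corrected
male	ln_fvc	young	weight	-0.00138	corrected
male	ln_fvc	old	intercept	-13.094	corrected
male	ln_fvc	old	age_minus_knot	-0.007	corrected
male	ln_fvc	old	height	0.156	corrected
male	ln_fvc	old	height2	-0.00041	corrected
male	ln_fvc	old	weight	-0.00138	corrected
female	ln_fvc	young	intercept	-11.355	corrected
female	ln_fvc	young	age	0.0338	corrected
female	ln_fvc	young	height	0.13	corrected
female	ln_fvc	young	height2	-0.00035	corrected
female	ln_fvc	young	weight	-0.00107	corrected
female	ln_fvc	old	intercept	-10.509	corrected
female	ln_fvc	old	age_minus_knot	-0.0079	corrected
female	ln_fvc	old	height	0.13	corrected
female	ln_fvc	old	height2	-0.00035	corrected
female	ln_fvc	old	weight	-0.00107	corrected
male	ratio	all	intercept	86.07	corrected
male	ratio	all	age	-0.0707	corrected
female	ratio	all	intercept	105.38	corrected
female	ratio	all	age	-0.7852	corrected
female	ratio	all	age2	0.0069	corrected
male	fev1	young	intercept	-25.857	as_printed
male	fev1	young	age	0.0285	as_printed
male	fev1	young	height	0.296	as_printed
male	fev1	young	height2	-0.000728	as_printed
male	fev1	old	intercept	-25.144	as_printed
male	fev1	old	age_minus_knot	-0.0288	as_printed
male	fev1	old	height	0.296	as_printed
male	fev1	old	height2	-0.000728	as_printed
female	fev1	young	intercept	-2.546	as_printed
female	fev1	young	age	0.0082	as_printed
female	fev1	young	height	0.0343	as_printed
female	fev1	old	intercept	-2.342	as_printed
female	fev1	old	age_minus_knot	-0.0232	as_printed
female	fev1	old	height	0.0343	as_printed
male	ln_fvc	young	intercept	-13.518	as_printed
male	ln_fvc	young	age	0.0196	as_printed
male	ln_fvc	young	height	0.156	as_printed
male	ln_fvc	young	height2	0.00041	as_printed
male	ln_fvc	young	weight	-0.00138	as_printed
male	ln_fvc	old	intercept	-13.094	as_printed
male	ln_fvc	old	age_minus_knot	-0.007	as_printed
male	ln_fvc	old	height	0.156	as_printed
male	ln_fvc	old	height2	-0.00041	as_printed
male	ln_fvc	old	weight	-0.00138	as_printed
female	ln_fvc	young	intercept	-11.355	as_printed
female	ln_fvc	young	age	0.0338	as_printed
female	ln_fvc	young	height	0.13	as_printed
female	ln_fvc	young	height2	-0.00035	as_printed
female	ln_fvc	young	weight	-0.00107	as_printed
female	ln_fvc	old	intercept	-10.509	as_printed
female	ln_fvc	old	age_minus_knot	-0.0079	as_printed
female	ln_fvc	old	height	0.13	as_printed
female	ln_fvc	old	height2	-0.00035	as_printed
female	ln_fvc	old	weight	-0.00107	as_printed
male	ratio	all	intercept	86.07	as_printed
male	ratio	all	age	-0.0707	as_printed
female	ratio	all	intercept	105.38	as_printed
female	ratio	all	age	-0.7852	as_printed
female	ratio	all	age2	0.0069	as_printed
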