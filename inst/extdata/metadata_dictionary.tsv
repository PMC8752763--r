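column	type	required	allowed	description
sample_id	string	yes		unique sample identifier
subject_id	string	yes		child identifier; repeated across a child's longitudinal samples
age_months	real	yes	> 0	age at sampling, months (never converted to days internally)
care_setting	enum	yes	daycare,homecare	care setting of the child
facility	string	daycare only	e.g. A-D	day-care facility label; must be empty for homecare samples
class_id	string	daycare only	e.g. A1,B2	facility+class label; must be empty for homecare samples
timepoint	integer	daycare only	1-5	sampling point (1 = entry; 2-5 = 2, 4, 7, 10 months after); empty for homecare
sex	enum	no	male,female	child sex
delivery_mode	enum	no	vaginal,cesarean	mode of delivery
breastfed_ever	boolean	no	true,false	ever breastfed
breastfeeding_current	boolean	no	true,false	still breastfed at sampling
household_size	integer	no	>= 1	persons in the household
peripartum_antibiotics	boolean	no	true,false	antibiotics during or within 3 days of delivery
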