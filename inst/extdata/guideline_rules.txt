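# Diet guideline rule base (SWRL-like, function-free Datalog).
# One rule per line:  id: Body1(?x) ^ Body2(?x,?v) -> Head(?x) @ "provenance"
# Unary predicates are ontology classes; binary predicates are ABox
# properties (food nutrient values are attached per 100 g at KB load).

# ---- MIND diet classification ------------------------------------------------
mind.enc.vegetables: Vegetables(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.berries: Berries(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.nuts: Nuts(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.oliveoil: OliveOil(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.wholegrains: WholeGrains(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.fish: Fish(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.beans: Beans(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.enc.poultry: Poultry(?f) -> MindEncouraged(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
mind.lim.butter: Butter(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
mind.lim.margarine: Margarine(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
mind.lim.cheese: Cheese(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
mind.lim.redmeat: RedMeat(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
mind.lim.friedfood: FriedFood(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
mind.lim.pastries: Pastries(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
mind.lim.sweets: Sweets(?f) -> MindLimited(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"

# ---- numeric meal constraints ------------------------------------------------
hhs.meal.range: meal_energy_kcal(?m, ?e) ^ ge(?e, 800) ^ le(?e, 850) -> HhsMealOk(?m) @ "HHS Dietary Guidelines: one meal should contain 800-850 kcal for a man on three meals per day"
ada.dinner.target: patient_eer(?p, ?r) ^ mul(?r, 0.25, ?t) -> dinner_target_kcal(?p, ?t) @ "ADA Diabetes Guidelines: dinner total calories 25% of Estimated Energy Requirement"
ada.protein.band: meal_energy_kcal(?m, ?e) ^ meal_protein_g(?m, ?g) ^ mul(?g, 4, ?pe) ^ mul(?e, 0.2, ?lo) ^ mul(?e, 0.3, ?hi) ^ ge(?pe, ?lo) ^ le(?pe, ?hi) -> AdaProteinOk(?m) @ "ADA Diabetes Guidelines: protein 20-30% of meal energy"
ada.sugar.cap: meal_energy_kcal(?m, ?e) ^ meal_sugar_g(?m, ?s) ^ mul(?s, 4, ?se) ^ mul(?e, 0.1, ?cap) ^ lt(?se, ?cap) -> AdaSugarOk(?m) @ "ADA Diabetes Guidelines: sugar less than 10% of meal energy"
eer.meal.split: patient_eer(?p, ?r) ^ meals_per_day(?p, ?n) ^ div(?r, ?n, ?t) -> meal_target_kcal(?p, ?t) @ "EER-based target: daily energy requirement split evenly across meals, within 10%"

# ---- profile exclusions --------------------------------------------------------
excl.allergy: allergic_to(?p, ?a) ^ contains(?r, ?a) -> Excluded(?p, ?r) @ "patient profile: allergy exclusion"
excl.religious: religious_exclusion(?p, ?a) ^ contains(?r, ?a) -> Excluded(?p, ?r) @ "patient profile: religious constraint"
excl.dislike: dislikes(?p, ?a) ^ contains(?r, ?a) -> Disfavored(?p, ?r) @ "patient profile: disliked food"

# ---- caregiver feasibility ----------------------------------------------------
care.time: prep_time_min(?r, ?t) ^ caregiver_time_limit(?c, ?l) ^ le(?t, ?l) -> TimeOk(?r, ?c) @ "caregiver profile: cooking time limit"
care.budget: cost_per_meal(?r, ?x) ^ caregiver_budget(?c, ?b) ^ le(?x, ?b) -> BudgetOk(?r, ?c) @ "caregiver profile: per-meal budget"

# ---- snack suitability ---------------------------------------------------------
snack.good: SnackFood(?f) ^ MindEncouraged(?f) -> GoodSnack(?f) @ "MIND diet: encourages vegetables, berries, nuts, olive oil, whole grains, fish, beans, poultry"
snack.caution: SnackFood(?f) ^ MindLimited(?f) -> CautionSnack(?f) @ "MIND diet: limit butter and margarine, cheese, red meat, fried food, pastries, sweets"
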