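rxcui,ndc,drug_name,drug_class
310001,50111-0648-01,sertraline 50 mg oral tablet,SSRI
310001,0049-4960-66,sertraline 50 mg tablet,SSRI
310002,0777-3105-02,fluoxetine 20 mg oral capsule,SSRI
310002,59762-3722-1,fluoxetine 20 mg capsule,SSRI
310003,0456-2010-01,escitalopram 10 mg oral tablet,SSRI
310003,65862-374-30,escitalopram 10 mg tablet,SSRI
310004,0378-6233-91,citalopram 20 mg oral tablet,SSRI
310004,68462-139-05,citalopram 20 mg tablet,SSRI
310005,0029-3211-13,paroxetine 20 mg oral tablet,SSRI
310005,60505-0168-1,paroxetine 20 mg tablet,SSRI
310006,51224-107-50,fluvoxamine 50 mg oral tablet,SSRI
310006,0093-5234-01,fluvoxamine 50 mg tablet,SSRI
310011,0002-3235-30,duloxetine 30 mg delayed release capsule,SNRI
310011,64764-300-30,duloxetine 30 mg capsule,SNRI
310012,0008-0833-01,venlafaxine 75 mg extended release capsule,SNRI
310012,68180-101-06,venlafaxine 75 mg capsule,SNRI
310013,0087-0735-31,bupropion 150 mg extended release tablet,atypical antidepressant
310013,47781-356-01,bupropion 150 mg tablet,atypical antidepressant
310014,0052-0105-30,mirtazapine 15 mg oral tablet,atypical antidepressant
310014,65862-165-30,mirtazapine 15 mg tablet,atypical antidepressant
310015,50111-0560-01,trazodone 50 mg oral tablet,atypical antidepressant
310015,0093-0031-01,trazodone 50 mg tablet,atypical antidepressant
310021,59148-0007-13,aripiprazole 5 mg oral tablet,antipsychotic
310021,0378-6055-91,aripiprazole 5 mg tablet,antipsychotic
310022,50458-0593-01,risperidone 1 mg oral tablet,antipsychotic
310022,65862-602-01,risperidone 1 mg tablet,antipsychotic
310023,0310-0271-10,quetiapine 50 mg oral tablet,antipsychotic
310023,60505-3128-3,quetiapine 50 mg tablet,antipsychotic
310031,0078-0440-05,methylphenidate 18 mg extended release tablet,stimulant
310031,49884-471-01,methylphenidate 18 mg tablet,stimulant
310032,0002-3227-30,atomoxetine 40 mg oral capsule,ADHD nonstimulant
310032,63304-970-30,atomoxetine 40 mg capsule,ADHD nonstimulant
310033,52152-0105-02,guanfacine 1 mg extended release tablet,ADHD nonstimulant
310033,13668-216-30,guanfacine 1 mg tablet,ADHD nonstimulant
310034,0591-0460-01,clonidine 0.1 mg oral tablet,ADHD nonstimulant
310034,68382-695-01,clonidine 0.1 mg tablet,ADHD nonstimulant
310041,0069-5410-66,hydroxyzine 25 mg oral tablet,anxiolytic
310041,68462-497-01,hydroxyzine 25 mg tablet,anxiolytic
310042,0087-0822-31,buspirone 10 mg oral tablet,anxiolytic
310042,29300-246-01,buspirone 10 mg tablet,anxiolytic
310051,0173-0633-02,lamotrigine 25 mg oral tablet,mood stabilizer
310051,68180-352-06,lamotrigine 25 mg tablet,mood stabilizer
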