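condition,id,prompt
stress,s1,"Describe a situation in which another person criticized you harshly. How did you react?"
stress,s2,"Explain why you would be the right person for a demanding leadership position, and name your greatest weakness."
stress,s3,"Describe a moment when you failed at something important. What would you do differently?"
control,c1,"Which season of the year do you like best? Describe activities you enjoy during that time."
control,c2,"Describe a meal you like to cook or eat, and what you enjoy about it."
control,c3,"Tell us about a place you like to visit and what makes it pleasant."
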